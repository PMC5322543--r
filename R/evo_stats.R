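# Divergence statistics: expression correlation between paralogs, rank-based
# group contrasts, 2x2 chi-square tests, and an NG86 Ka/Ks estimator.
#
# Ka/Ks follows Nei & Gojobori (1986): per-codon synonymous site fractions
# counted over the three single-base neighbours at each position (mutations
# to stop codons count as nonsynonymous), site totals averaged over the two
# sequences, synonymous/nonsynonymous differences averaged over all
# evolutionary pathways between multi-hit codons (pathways passing through a
# stop codon excluded unless all are blocked), and proportions converted to
# distances with the Jukes-Cantor correction d = -(3/4) ln(1 - 4p/3).

#' Pearson correlation with pairwise deletion
#'
#' @param x,y numeric vectors of equal length; entries where either is `NA`
#'   are dropped. At least 3 complete pairs and nonzero variance in both
#'   vectors are required; otherwise `NA` is returned with a warning.
#' @return correlation coefficient in `[-1, 1]`, or `NA`.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !(is.na(x) | is.na(y))
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) {
    warning("fewer than 3 complete pairs; correlation undefined")
    return(NA_real_)
  }
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    warning("zero variance; correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y)
}

#' Compare expression correlations between same and divergent groups
#'
#' Two-sided Mann-Whitney U test. Exact enumeration is used for small
#' samples (both groups <= 20) without ties; otherwise the normal
#' approximation with tie correction.
#'
#' @param same,divergent numeric vectors of per-pair correlation
#'   coefficients; `NA` entries are dropped.
#' @return list with `p_value`, `statistic` (U for the `divergent` sample),
#'   `method`, group sizes, group medians and `direction`.
#' @export
compare_correlation_groups <- function(same, divergent) {
  same <- same[!is.na(same)]
  divergent <- divergent[!is.na(divergent)]
  if (length(same) == 0 || length(divergent) == 0) {
    stop("both groups must be nonempty")
  }
  ties <- anyDuplicated(c(same, divergent)) > 0
  exact <- max(length(same), length(divergent)) <= 20 && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(divergent, same, alternative = "two.sided",
                       exact = exact, correct = FALSE)
  )
  med_s <- median(same); med_d <- median(divergent)
  list(p_value = wt$p.value, statistic = unname(wt$statistic),
       method = if (exact) "exact" else "normal approximation",
       n_same = length(same), n_divergent = length(divergent),
       median_same = med_s, median_divergent = med_d,
       direction = if (med_d < med_s) "divergent < same"
                   else if (med_d > med_s) "divergent > same" else "equal")
}

#' Chi-square test of independence on a 2x2 table
#'
#' Pearson statistic with 1 degree of freedom; Yates continuity correction
#' off by default (the tables tested here have large expected counts).
#'
#' @param table 2x2 matrix of nonnegative integer counts with all row and
#'   column sums positive.
#' @param yates apply the continuity correction.
#' @return list with `statistic`, `p_value`, `df` and `expected`.
#' @export
chi_square_2x2 <- function(table, yates = FALSE) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2, 2)), all(table >= 0))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("test undefined: zero marginal")
  }
  ct <- suppressWarnings(stats::chisq.test(table, correct = yates))
  list(statistic = unname(ct$statistic), p_value = ct$p.value,
       df = unname(ct$parameter), expected = ct$expected, yates = yates)
}

.GENETIC_CODE_RNA <- local({
  gc <- Biostrings::GENETIC_CODE
  names(gc) <- chartr("T", "U", names(gc))
  gc
})

.codons <- function(seq) {
  seq <- .normalize_seq(seq, "rna")
  n <- nchar(seq)
  if (n %% 3 != 0) stop("sequence length ", n, " not divisible by 3")
  substring(seq, seq(1, n, 3), seq(3, n, 3))
}

#' Translate a coding sequence
#'
#' Standard genetic code; `*` for stop codons. Codons containing characters
#' other than A/C/G/U(T) translate to `X`.
#'
#' @param seq in-frame coding sequence (RNA or DNA alphabet).
#' @return single amino-acid string.
#' @export
translate_cds <- function(seq) {
  cods <- .codons(seq)
  aa <- .GENETIC_CODE_RNA[cods]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Thread coding sequences through a protein alignment
#'
#' Expands each protein alignment gap into a codon (3-nt) gap so that the
#' two coding sequences become an aligned codon matrix. Translations must
#' match the degapped alignment rows.
#'
#' @param aln_a,aln_b gapped protein alignment rows (`-` for gaps) of equal
#'   length.
#' @param cds_a,cds_b in-frame coding sequences (a trailing stop codon is
#'   tolerated and dropped).
#' @return list of class `codon_alignment` with gapped nucleotide rows
#'   `a` and `b`.
#' @export
align_codons <- function(aln_a, aln_b, cds_a, cds_b) {
  stopifnot(nchar(aln_a) == nchar(aln_b))
  thread <- function(aln, cds, label) {
    cods <- .codons(cds)
    aa <- .GENETIC_CODE_RNA[cods]
    aa[is.na(aa)] <- "X"
    if (length(aa) && aa[length(aa)] == "*") {
      cods <- cods[-length(cods)]
      aa <- aa[-length(aa)]
    }
    cols <- strsplit(aln, "", fixed = TRUE)[[1]]
    res <- cols[cols != "-"]
    if (length(res) != length(cods)) {
      stop("alignment row ", label, " has ", length(res),
           " residues but the CDS encodes ", length(cods), " codons")
    }
    mism <- which(res != aa)
    if (length(mism)) {
      stop("translation mismatch in row ", label, " at codon ", mism[1],
           " ('", aa[mism[1]], "' vs aligned '", res[mism[1]], "')")
    }
    out <- character(length(cols))
    out[cols == "-"] <- "---"
    out[cols != "-"] <- cods
    paste(out, collapse = "")
  }
  structure(list(a = thread(aln_a, cds_a, "a"), b = thread(aln_b, cds_b, "b")),
            class = "codon_alignment")
}

#' Globally align two paralogous coding sequences at the codon level
#'
#' Translates both sequences, aligns the proteins globally (BLOSUM62,
#' affine gaps) and back-threads the codons through the protein alignment.
#'
#' @param cds_a,cds_b in-frame coding sequences.
#' @param gap_opening,gap_extension affine gap penalties for the protein
#'   alignment.
#' @return a `codon_alignment` (see [align_codons()]).
#' @export
align_paralog_cds <- function(cds_a, cds_b, gap_opening = 10,
                              gap_extension = 0.5) {
  strip_stop <- function(s) {
    aa <- translate_cds(s)
    if (endsWith(aa, "*")) substr(aa, 1, nchar(aa) - 1) else aa
  }
  pa <- strip_stop(cds_a)
  pb <- strip_stop(cds_b)
  if (grepl("\\*", pa) || grepl("\\*", pb)) {
    stop("internal stop codon in input CDS")
  }
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(pa), Biostrings::AAString(pb),
    substitutionMatrix = "BLOSUM62", gapOpening = gap_opening,
    gapExtension = gap_extension, type = "global"
  )
  align_codons(as.character(Biostrings::pattern(aln)),
               as.character(Biostrings::subject(aln)),
               cds_a, cds_b)
}

# per-codon count of synonymous sites: at each position, the fraction of the
# 3 possible single-base changes that preserve the amino acid
.syn_sites <- function(codon) {
  aa <- .GENETIC_CODE_RNA[[codon]]
  bases <- strsplit(codon, "", fixed = TRUE)[[1]]
  s <- 0
  for (k in 1:3) {
    for (b in setdiff(c("A", "C", "G", "U"), bases[k])) {
      nb <- bases; nb[k] <- b
      if (identical(.GENETIC_CODE_RNA[[paste(nb, collapse = "")]], aa)) {
        s <- s + 1 / 3
      }
    }
  }
  s
}

# pathway-averaged (syn, nonsyn) difference counts between two codons
.path_diffs <- function(c1, c2) {
  b1 <- strsplit(c1, "", fixed = TRUE)[[1]]
  b2 <- strsplit(c2, "", fixed = TRUE)[[1]]
  pos <- which(b1 != b2)
  nd <- length(pos)
  if (nd == 0) return(c(0, 0))
  perms <- if (nd == 1) list(pos) else {
    if (nd == 2) list(pos, rev(pos)) else {
      p <- pos
      list(p[c(1, 2, 3)], p[c(1, 3, 2)], p[c(2, 1, 3)],
           p[c(2, 3, 1)], p[c(3, 1, 2)], p[c(3, 2, 1)])
    }
  }
  walk <- function(order) {
    cur <- b1
    syn <- 0; non <- 0; blocked <- FALSE
    for (k in order) {
      aa_from <- .GENETIC_CODE_RNA[[paste(cur, collapse = "")]]
      cur[k] <- b2[k]
      nxt <- paste(cur, collapse = "")
      aa_to <- .GENETIC_CODE_RNA[[nxt]]
      if (aa_to == "*" && nxt != c2) blocked <- TRUE
      if (identical(aa_from, aa_to)) syn <- syn + 1 else non <- non + 1
    }
    list(syn = syn, non = non, blocked = blocked)
  }
  walks <- lapply(perms, walk)
  ok <- !vapply(walks, `[[`, logical(1), "blocked")
  if (any(ok)) walks <- walks[ok]
  c(mean(vapply(walks, `[[`, numeric(1), "syn")),
    mean(vapply(walks, `[[`, numeric(1), "non")))
}

#' NG86 Ka/Ks from a codon alignment
#'
#' Columns with a gap or ambiguity in either codon are dropped; internal
#' stop codons are an error. Proportions are corrected with Jukes-Cantor;
#' a proportion >= 3/4 is flagged saturated and yields `NA` for the
#' corresponding rate.
#'
#' @param aln a `codon_alignment` from [align_codons()] or
#'   [align_paralog_cds()], or a list/vector of two equal-length gapped
#'   nucleotide strings.
#' @return list of class `pair_stats` with `ka`, `ks`, `ka_ks`, site and
#'   difference counts (`S`, `N`, `Sd`, `Nd`), raw proportions (`ps`,
#'   `pn`), `n_codons` used and saturation flags.
#' @export
ng86_ka_ks <- function(aln) {
  if (inherits(aln, "codon_alignment")) {
    a <- aln$a; b <- aln$b
  } else {
    stopifnot(length(aln) == 2)
    a <- aln[[1]]; b <- aln[[2]]
  }
  a <- .normalize_seq(a, "rna"); b <- .normalize_seq(b, "rna")
  stopifnot(nchar(a) == nchar(b))
  ca <- .codons(chartr("-", "N", a))
  cb <- .codons(chartr("-", "N", b))
  keep <- grepl("^[ACGU]{3}$", ca) & grepl("^[ACGU]{3}$", cb)
  ca <- ca[keep]; cb <- cb[keep]
  if (length(ca) == 0) {
    return(structure(list(ka = NA_real_, ks = NA_real_, ka_ks = NA_real_,
                          S = NA_real_, N = NA_real_, Sd = NA_real_,
                          Nd = NA_real_, ps = NA_real_, pn = NA_real_,
                          n_codons = 0L, saturated_s = NA, saturated_n = NA,
                          undefined = TRUE, method = "NG86+JC"),
                     class = "pair_stats"))
  }
  if (any(.GENETIC_CODE_RNA[ca] == "*") || any(.GENETIC_CODE_RNA[cb] == "*")) {
    stop("internal stop codon in alignment")
  }
  syn_tab <- vapply(unique(c(ca, cb)), .syn_sites, numeric(1))
  S <- (sum(syn_tab[ca]) + sum(syn_tab[cb])) / 2
  N <- 3 * length(ca) - S
  diffs <- mapply(.path_diffs, ca, cb)
  Sd <- sum(diffs[1, ]); Nd <- sum(diffs[2, ])
  ps <- if (S > 0) Sd / S else 0
  pn <- if (N > 0) Nd / N else 0
  jc <- function(p) if (p >= 3 / 4) NA_real_ else -3 / 4 * log(1 - 4 * p / 3)
  ks <- jc(ps); ka <- jc(pn)
  structure(list(
    ka = ka, ks = ks,
    ka_ks = if (!is.na(ka) && !is.na(ks) && ks > 0) ka / ks else NA_real_,
    S = S, N = N, Sd = Sd, Nd = Nd, ps = ps, pn = pn,
    n_codons = length(ca), saturated_s = ps >= 3 / 4, saturated_n = pn >= 3 / 4,
    undefined = FALSE, method = "NG86+JC"
  ), class = "pair_stats")
}
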