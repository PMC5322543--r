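# Duplex scoring: miRNA position i (from the 5' end) pairs antiparallel with
# window position L+1-i on the transcript sense strand. Watson-Crick pairs
# cost 0, G:U wobbles cost `wobble_penalty` (default 0.5 points), all other
# pairings cost `mismatch_penalty` (default 1 point). Coordinates are 1-based
# fully-closed intervals on the transcript sense strand.

# pairing-class lookup: rows = miRNA base, cols = transcript base
# (A,C,G,U,N); 0 = Watson-Crick, 1 = G:U wobble, 2 = mismatch
.PAIR_CLASS <- local({
  m <- matrix(2L, 5, 5, dimnames = list(RNA_ALPHABET, RNA_ALPHABET))
  wc <- rbind(c("A", "U"), c("U", "A"), c("G", "C"), c("C", "G"))
  m[wc] <- 0L
  m[rbind(c("G", "U"), c("U", "G"))] <- 1L
  m
})

.encode_seq <- function(s) {
  code <- match(strsplit(s, "", fixed = TRUE)[[1]], RNA_ALPHABET)
  if (anyNA(code)) stop("sequence contains characters outside {A,C,G,U,N}")
  code
}

#' Define a binding-site scoring profile
#'
#' A profile is one configuration of the weighted-mismatch scheme: a score
#' cutoff `C` (sites with score <= C are reported), penalties per G:U wobble
#' and per non-G:U mismatch, and an optional seed interval (miRNA positions
#' counted from the 5' end) where penalties are up-weighted. In-seed
#' penalties default to `seed_multiplier` times the base penalty and can be
#' overridden per pairing class.
#'
#' @param name profile label.
#' @param cutoff maximum reported score, in points; must be >= 0.
#' @param wobble_penalty points per G:U pair.
#' @param mismatch_penalty points per non-G:U mismatch (also applied when a
#'   position holds `N`).
#' @param seed_range integer vector of miRNA positions weighted extra, or
#'   `NULL` for no seed weighting.
#' @param seed_multiplier factor (>= 1) applied to penalties inside
#'   `seed_range`.
#' @param seed_wobble_penalty,seed_mismatch_penalty explicit in-seed
#'   penalties, overriding the multiplier for that class.
#' @return object of class `scan_profile`.
#' @export
scan_profile <- function(name, cutoff, wobble_penalty = 0.5,
                         mismatch_penalty = 1, seed_range = NULL,
                         seed_multiplier = 1, seed_wobble_penalty = NULL,
                         seed_mismatch_penalty = NULL) {
  stopifnot(cutoff >= 0, wobble_penalty >= 0, mismatch_penalty >= 0,
            seed_multiplier >= 1)
  if (!is.null(seed_range)) {
    seed_range <- as.integer(seed_range)
    stopifnot(all(seed_range >= 1))
  }
  structure(
    list(name = name, cutoff = cutoff, wobble_penalty = wobble_penalty,
         mismatch_penalty = mismatch_penalty, seed_range = seed_range,
         seed_multiplier = seed_multiplier,
         seed_wobble_penalty = seed_wobble_penalty,
         seed_mismatch_penalty = seed_mismatch_penalty),
    class = "scan_profile"
  )
}

#' Default scoring profiles for the 2-of-3 consensus
#'
#' Three deliberately distinct configurations of the point scheme:
#' \describe{
#'   \item{plain}{no positional weighting, cutoff 3.0.}
#'   \item{seed}{penalties doubled at miRNA positions 2-13, cutoff 3.5.}
#'   \item{wobble_strict}{G:U counted 1.0 point inside positions 2-13 and
#'     0.5 elsewhere, cutoff 3.0.}
#' }
#' These emulate running several plant target predictors that share the
#' wobble/mismatch point scheme but weight the 5' pairing region
#' differently; they are configuration, not reproductions of any external
#' tool.
#'
#' @return named list of three `scan_profile` objects.
#' @export
default_profiles <- function() {
  list(
    plain = scan_profile("plain", 3),
    seed = scan_profile("seed", 3.5, seed_range = 2:13, seed_multiplier = 2),
    wobble_strict = scan_profile("wobble_strict", 3, seed_range = 2:13,
                                 seed_wobble_penalty = 1)
  )
}

#' Define a k-of-n consensus rule
#'
#' @param profiles list of [scan_profile()] objects.
#' @param k minimum number of agreeing profiles for a consensus call.
#' @return object of class `consensus_rule`.
#' @export
consensus_rule <- function(profiles = default_profiles(), k = 2) {
  stopifnot(length(profiles) >= 1, k >= 1, k <= length(profiles))
  structure(list(profiles = profiles, k = as.integer(k)),
            class = "consensus_rule")
}

# L x 3 penalty matrix for a profile: row = miRNA position, cols = pairing
# class (WC, wobble, mismatch)
.profile_penalties <- function(profile, L) {
  W <- cbind(0, rep(profile$wobble_penalty, L), rep(profile$mismatch_penalty, L))
  sr <- profile$seed_range
  if (!is.null(sr)) {
    sr <- sr[sr <= L]
    W[sr, 2] <- profile$seed_wobble_penalty %||%
      (profile$wobble_penalty * profile$seed_multiplier)
    W[sr, 3] <- profile$seed_mismatch_penalty %||%
      (profile$mismatch_penalty * profile$seed_multiplier)
  }
  W
}

# score every length-L window of tcode under each profile in one pass;
# returns n_windows x n_profiles matrix
.score_windows <- function(mcode, tcode, profiles) {
  L <- length(mcode)
  n <- length(tcode) - L + 1L
  np <- length(profiles)
  if (n < 1L) return(matrix(numeric(0), 0, np))
  Wl <- lapply(profiles, .profile_penalties, L = L)
  rm <- rev(mcode)
  scores <- matrix(0, n, np)
  for (j in seq_len(L)) {
    cls <- .PAIR_CLASS[rm[j], tcode[j:(j + n - 1L)]] + 1L
    i <- L + 1L - j  # miRNA position paired at this window offset
    for (p in seq_len(np)) {
      w <- Wl[[p]][i, ]
      scores[, p] <- scores[, p] + w[cls]
    }
  }
  scores
}

#' Score one miRNA/window duplex
#'
#' @param mirna a [mirna()] object (or mature RNA sequence string).
#' @param window RNA string of the same length as the mature miRNA, given
#'   5'->3' on the transcript sense strand.
#' @param profile a [scan_profile()].
#' @return score in points.
#' @export
score_duplex <- function(mirna, window, profile) {
  mseq <- if (inherits(mirna, "mirna")) mirna$mature else .normalize_seq(mirna, "rna")
  window <- .normalize_seq(window, "rna")
  if (nchar(mseq) != nchar(window)) {
    stop("window length ", nchar(window), " != miRNA length ", nchar(mseq))
  }
  .score_windows(.encode_seq(mseq), .encode_seq(window), list(profile))[1, 1]
}

#' Scan a transcript for binding sites under one profile
#'
#' Every window of miRNA length is scored; windows at or below the profile
#' cutoff are returned sorted by start. Overlapping hits are allowed.
#'
#' @param mirna a [mirna()] object.
#' @param tx a [transcript()] object.
#' @param profile a [scan_profile()].
#' @return data.frame with columns `start`, `end`, `score` (1-based closed
#'   coordinates).
#' @export
scan_transcript <- function(mirna, tx, profile) {
  stopifnot(inherits(mirna, "mirna"), inherits(tx, "transcript"))
  L <- nchar(mirna$mature)
  if (nchar(tx$seq) < L) {
    warning("transcript '", tx$gene_id, "' shorter than miRNA; no scan")
    return(data.frame(start = integer(0), end = integer(0), score = numeric(0)))
  }
  sc <- .score_windows(.encode_seq(mirna$mature), .encode_seq(tx$seq),
                       list(profile))[, 1]
  hit <- which(sc <= profile$cutoff)
  data.frame(start = hit, end = hit + L - 1L, score = sc[hit])
}

# cluster hit starts across profiles: single linkage, consecutive starts
# within floor(L/2) are one site (= >=50% reciprocal overlap for equal-length
# windows)
.cluster_starts <- function(starts, L) {
  us <- sort(unique(starts))
  if (length(us) == 0) return(integer(0))
  cl <- cumsum(c(1L, diff(us) > L %/% 2L))
  setNames(cl, us)
}

#' Consensus binding-site calls for one miRNA on one transcript
#'
#' The transcript is scanned under every profile of the rule; hits from
#' different profiles whose windows overlap by at least 50% reciprocally are
#' grouped into one candidate site. A site is consensus-positive when at
#' least `k` profiles contributed a hit. Each site is reported at a
#' representative window of exactly miRNA length: the member window with the
#' lowest plain (unweighted 0.5/1) score, ties broken toward the smallest
#' start. The reported `score` is that plain score.
#'
#' @param mirna a [mirna()] object.
#' @param tx a [transcript()] object.
#' @param rule a [consensus_rule()].
#' @return data.frame with columns `gene_id`, `mirna_id`, `family`, `start`,
#'   `end`, `score`, `n_agreeing`, `profiles`, per-profile logical columns,
#'   and `consensus`.
#' @export
consensus_call <- function(mirna, tx, rule) {
  stopifnot(inherits(rule, "consensus_rule"))
  profiles <- rule$profiles
  pnames <- vapply(profiles, `[[`, "", "name")
  L <- nchar(mirna$mature)
  empty <- data.frame(
    gene_id = character(0), mirna_id = character(0), family = character(0),
    start = integer(0), end = integer(0), score = numeric(0),
    n_agreeing = integer(0), profiles = character(0), consensus = logical(0)
  )
  if (nchar(tx$seq) < L) return(empty)
  plain <- scan_profile("unweighted", Inf)
  sc <- .score_windows(.encode_seq(mirna$mature), .encode_seq(tx$seq),
                       c(profiles, list(plain)))
  np <- length(profiles)
  hit_list <- lapply(seq_len(np), function(p) {
    which(sc[, p] <= profiles[[p]]$cutoff)
  })
  all_starts <- unlist(hit_list)
  if (length(all_starts) == 0) return(empty)
  cl_of <- .cluster_starts(all_starts, L)
  ncl <- max(cl_of)
  rows <- lapply(seq_len(ncl), function(ci) {
    members <- as.integer(names(cl_of)[cl_of == ci])
    agree <- vapply(hit_list, function(h) any(h %in% members), logical(1))
    plain_sc <- sc[members, np + 1L]
    best <- members[order(plain_sc, members)][1]
    data.frame(
      gene_id = tx$gene_id, mirna_id = mirna$id, family = mirna$family,
      start = best, end = best + L - 1L, score = sc[best, np + 1L],
      n_agreeing = sum(agree),
      profiles = paste(pnames[agree], collapse = ","),
      consensus = sum(agree) >= rule$k
    )
  })
  out <- do.call(rbind, rows)
  out[order(out$start), , drop = FALSE]
}

#' Genome-wide miRNA-target interaction table
#'
#' Runs [consensus_call()] for every miRNA/transcript combination and keeps
#' consensus-positive sites. An interaction is one (miRNA, gene) pair with
#' at least one consensus site; gene-level target status is having at least
#' one interaction.
#'
#' @param mirnas list of [mirna()] objects.
#' @param transcripts list of [transcript()] objects.
#' @param rule a [consensus_rule()].
#' @return list of class `target_table` with elements `sites` (all consensus
#'   sites), `interactions` (one row per miRNA-gene pair with `n_sites`),
#'   `target_genes` (character vector) and `summary` (counts and the mean
#'   number of sites per targeted gene), all sorted deterministically by
#'   (gene_id, start, mirna_id).
#' @export
target_table <- function(mirnas, transcripts, rule = consensus_rule()) {
  stopifnot(length(mirnas) > 0, length(transcripts) > 0)
  res <- vector("list", length(mirnas) * length(transcripts))
  idx <- 0L
  for (m in mirnas) {
    for (tx in transcripts) {
      cc <- consensus_call(m, tx, rule)
      cc <- cc[cc$consensus, , drop = FALSE]
      if (nrow(cc)) {
        idx <- idx + 1L
        res[[idx]] <- cc
      }
    }
  }
  sites <- if (idx) do.call(rbind, res[seq_len(idx)]) else data.frame(
    gene_id = character(0), mirna_id = character(0), family = character(0),
    start = integer(0), end = integer(0), score = numeric(0),
    n_agreeing = integer(0), profiles = character(0), consensus = logical(0)
  )
  sites <- sites[order(sites$gene_id, sites$start, sites$mirna_id), , drop = FALSE]
  rownames(sites) <- NULL
  if (nrow(sites)) {
    key <- paste(sites$mirna_id, sites$gene_id, sep = "\r")
    first <- !duplicated(key)
    interactions <- data.frame(
      mirna_id = sites$mirna_id[first], gene_id = sites$gene_id[first],
      family = sites$family[first],
      n_sites = as.integer(table(key)[key[first]])
    )
    interactions <- interactions[order(interactions$gene_id, interactions$mirna_id), ]
    rownames(interactions) <- NULL
  } else {
    interactions <- data.frame(mirna_id = character(0), gene_id = character(0),
                               family = character(0), n_sites = integer(0))
  }
  target_genes <- sort(unique(interactions$gene_id))
  per_gene <- if (length(target_genes)) {
    tapply(sites$start, sites$gene_id, length)
  } else integer(0)
  structure(
    list(sites = sites, interactions = interactions,
         target_genes = target_genes,
         summary = list(
           n_interactions = nrow(interactions),
           n_target_genes = length(target_genes),
           n_mirnas = length(unique(interactions$mirna_id)),
           mean_sites_per_target = if (length(per_gene)) mean(per_gene) else NA_real_
         )),
    class = "target_table"
  )
}

#' Per-gene miRNA family target sets from a target table
#'
#' By default the set elements are miRNA family keys, so two paralogs bound
#' by the same family anywhere count as matching. With
#' `coordinate_aware = TRUE` each element also carries the site's position
#' bin (`family@bin`), so the same family bound at distant positions in two
#' paralogs no longer matches.
#'
#' @param tt a [target_table()] result.
#' @param genes gene ids to include; genes without interactions get empty
#'   sets.
#' @param coordinate_aware append position bins to the family keys.
#' @param bin_width bin size in nucleotides for the coordinate-aware mode.
#' @return named list of character vectors.
#' @export
target_sets <- function(tt, genes, coordinate_aware = FALSE, bin_width = 50) {
  stopifnot(inherits(tt, "target_table"))
  if (coordinate_aware) {
    keys <- paste0(tt$sites$family, "@", ceiling(tt$sites$start / bin_width))
    sets <- split(keys, tt$sites$gene_id)
  } else {
    sets <- split(tt$interactions$family, tt$interactions$gene_id)
  }
  out <- lapply(genes, function(g) sort(unique(sets[[g]] %||% character(0))))
  names(out) <- genes
  out
}
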