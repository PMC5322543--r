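# Seeded generator producing every pipeline input with known ground truth.
#
# The generator emulates the real study inputs: a mature-miRNA set with
# known ages, transcript sequences with planted binding sites of controlled
# plain-profile score, duplicate pairs/triplets whose divergence status is
# forced by scheduled site loss or young-miRNA site gain, an all-vs-all
# similarity hit table encoding true duplicates and singletons, a
# cross-species homolog hit table consistent with the true miRNA ages, and
# an expression matrix whose within-pair correlation is coupled to the
# intended divergence verdict.
#
# Divergence mechanism per duplicate group: every group inherits one
# ancestral site (an ancient miRNA family) planted at the same position in
# all members. With probability `p_site_loss` the site is ablated in one
# member (>= 4 points of scheduled mismatch damage, putting it past every
# profile cutoff); otherwise, with probability `p_young_gain`, one member
# gains an extra site for a young miRNA. The expected divergent fraction is
# therefore p_site_loss + (1 - p_site_loss) * p_young_gain.

#' Generator configuration
#'
#' Defaults emulate the cohort the analysis was designed around: 63
#' expression conditions, 21-nt miRNAs, transcript GC ~ 0.4, and loss/gain
#' rates chosen so that ~91% of targeted duplicate groups are divergent
#' with ~51% of the divergence attributable to young miRNAs.
#'
#' @param seed integer seed; all randomness flows from it.
#' @param n_families number of miRNA families.
#' @param n_mirnas total mature miRNAs (distributed over families as
#'   lettered variants).
#' @param mirna_len mature miRNA length in nt.
#' @param n_pairs_wgd,n_pairs_td,n_triplets,n_singletons gene counts by
#'   group type.
#' @param tx_len mean transcript length in nt.
#' @param gc transcript GC fraction.
#' @param site_score_dist data.frame with columns `score`, `prob`: the
#'   distribution of planted plain-profile site scores.
#' @param p_site_loss per-group probability that the ancestral site is
#'   ablated in one member.
#' @param p_young_gain probability (given no loss) that one member gains a
#'   young-miRNA site.
#' @param p_family_young fraction of miRNA families that are young.
#' @param rho_same,rho_div expression correlation for same/divergent groups.
#' @param n_conditions number of expression columns.
#' @return list of class `gen_config`.
#' @export
gen_config <- function(seed = 1, n_families = 16, n_mirnas = 24,
                       mirna_len = 21, n_pairs_wgd = 120, n_pairs_td = 50,
                       n_triplets = 30, n_singletons = 60, tx_len = 500,
                       gc = 0.4,
                       site_score_dist = data.frame(
                         score = c(0, 0.5, 1, 1.5, 2, 2.5),
                         prob = c(0.5, 0.1, 0.1, 0.1, 0.1, 0.1)),
                       p_site_loss = 0.45, p_young_gain = 0.84,
                       p_family_young = 0.5, rho_same = 0.8, rho_div = 0.2,
                       n_conditions = 63) {
  stopifnot(p_site_loss >= 0, p_site_loss <= 1, p_young_gain >= 0,
            p_young_gain <= 1, p_family_young > 0, p_family_young < 1,
            rho_same > -1, rho_same < 1, rho_div > -1, rho_div < 1,
            n_families >= 2, n_mirnas >= n_families, mirna_len >= 15,
            mirna_len <= 30, gc > 0, gc < 1, n_conditions >= 3,
            abs(sum(site_score_dist$prob) - 1) < 1e-8)
  if (tx_len < 3 * mirna_len) stop("tx_len too short for planting sites")
  structure(as.list(environment()), class = "gen_config")
}

.random_seq <- function(n, len, gc) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, U = (1 - gc) / 2)
  vapply(seq_len(n), function(i) {
    paste(sample(names(p), len, replace = TRUE, prob = p), collapse = "")
  }, character(1))
}

# a miRNA is "plantable" when enough non-seed positions (1 and 14..L) can
# host a G:U wobble (miRNA base G or U)
.plantable <- function(seq, L) {
  b <- strsplit(seq, "", fixed = TRUE)[[1]]
  out_seed <- c(1, 14:L)
  sum(b[out_seed] %in% c("G", "U")) >= 2
}

# build a site window with an exact plain-profile score, damaging only
# non-seed miRNA positions so that all default profiles still call the site
.plant_window <- function(mirna_seq, score) {
  L <- nchar(mirna_seq)
  mb <- strsplit(mirna_seq, "", fixed = TRUE)[[1]]
  window <- strsplit(reverse_complement(mirna_seq), "", fixed = TRUE)[[1]]
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  wobble_partner <- c(G = "U", U = "G", A = NA, C = NA)
  out_seed <- c(1, 14:L)
  n_mm <- floor(score)
  use_wobble <- (score - n_mm) > 0
  pos_pool <- sample(out_seed)
  used <- integer(0)
  if (use_wobble) {
    cand <- pos_pool[mb[pos_pool] %in% c("G", "U")]
    if (length(cand) == 0) stop("no wobble-capable position outside the seed")
    i <- cand[1]
    window[L + 1 - i] <- wobble_partner[[mb[i]]]
    used <- i
  }
  mm_pos <- setdiff(pos_pool, used)[seq_len(n_mm)]
  for (i in mm_pos) {
    bad <- setdiff(c("A", "C", "G", "U"),
                   c(comp[[mb[i]]], wobble_partner[[mb[i]]]))
    window[L + 1 - i] <- sample(bad, 1)
  }
  paste(window, collapse = "")
}

# ablate a planted window: 4 mismatches at seed positions that currently
# pair Watson-Crick, pushing the score past every default cutoff
.ablate_window <- function(mirna_seq, window, n_damage = 4) {
  L <- nchar(mirna_seq)
  mb <- strsplit(mirna_seq, "", fixed = TRUE)[[1]]
  wb <- strsplit(window, "", fixed = TRUE)[[1]]
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  wobble_partner <- c(G = "U", U = "G", A = NA, C = NA)
  wc <- which(wb[L + 1 - seq_len(L)] == comp[mb])  # miRNA positions paired WC
  pos <- sample(wc, min(n_damage, length(wc)))
  for (i in pos) {
    bad <- setdiff(c("A", "C", "G", "U"),
                   c(comp[[mb[i]]], wobble_partner[[mb[i]]]))
    wb[L + 1 - i] <- sample(bad, 1)
  }
  paste(wb, collapse = "")
}

.splice_in <- function(tx, window, pos) {
  paste0(substr(tx, 1, pos - 1), window,
         substr(tx, pos + nchar(window), nchar(tx)))
}

# correlated nonnegative expression rows for one group (compound-symmetric
# correlation rho, mean 8, sd 2, shifted up if any draw goes negative)
.expr_rows <- function(m, n_cond, rho) {
  sigma <- matrix(rho, m, m); diag(sigma) <- 1
  z <- matrix(rnorm(m * n_cond), m, n_cond)
  x <- t(chol(sigma)) %*% z * 2 + 8
  shift <- min(x)
  if (shift < 0) x <- x - shift
  x
}

#' Generate a synthetic dataset bundle with ground truth
#'
#' Deterministic for a fixed `config$seed`. See the package source header
#' of this file for the generative model.
#'
#' @param config a [gen_config()].
#' @return list of class `synth_bundle` with elements `mirnas` (data.frame
#'   id/family/age/seq), `mirna_seqs`, `transcripts` (named sequence
#'   vector), `hits` (similarity hits), `groups` (group label table),
#'   `homolog_hits`, `expression` (matrix genes x conditions), `truth`
#'   (list: `groups`, `sites`, `mirna_age`, `gene_status`) and `config`.
#' @export
generate_dataset <- function(config = gen_config()) {
  stopifnot(inherits(config, "gen_config"))
  set.seed(config$seed)
  L <- config$mirna_len

  # --- miRNAs: families with lettered variants, ages per family ---
  fam_ids <- sprintf("syn-miR%03d", seq_len(config$n_families))
  n_young <- max(1, round(config$p_family_young * config$n_families))
  fam_age <- rep("ancient", config$n_families)
  fam_age[sample(config$n_families, n_young)] <- "young"
  fam_of <- rep(seq_len(config$n_families), length.out = config$n_mirnas)
  variant <- stats::ave(fam_of, fam_of, FUN = seq_along)
  mir_ids <- paste0(fam_ids[fam_of], letters[variant])
  mir_seq <- character(config$n_mirnas)
  for (i in seq_len(config$n_mirnas)) {
    repeat {
      s <- .random_seq(1, L, 0.5)
      if (.plantable(s, L)) break
    }
    mir_seq[i] <- s
  }
  mirnas_df <- data.frame(id = mir_ids, family = fam_ids[fam_of],
                          age = fam_age[fam_of], seq = mir_seq)

  # --- genes and groups ---
  n_groups <- config$n_pairs_wgd + config$n_pairs_td + config$n_triplets
  sizes <- c(rep(2L, config$n_pairs_wgd + config$n_pairs_td),
             rep(3L, config$n_triplets))
  classes <- c(rep("WGD", config$n_pairs_wgd), rep("TD", config$n_pairs_td),
               rep("triplet", config$n_triplets))
  n_genes <- sum(sizes) + config$n_singletons
  gene_ids <- sprintf("SYNG%05d", seq_len(n_genes))
  lens <- pmax(3L * L, round(rnorm(n_genes, config$tx_len, config$tx_len * 0.1)))
  tx <- setNames(vapply(seq_len(n_genes), function(i) {
    .random_seq(1, lens[i], config$gc)
  }, character(1)), gene_ids)

  gi <- 0L
  group_rows <- vector("list", n_groups)
  truth_groups <- vector("list", n_groups)
  site_rows <- list()
  hit_rows <- list()
  ancient_mirs <- which(mirnas_df$age == "ancient")
  young_mirs <- which(mirnas_df$age == "young")
  if (length(ancient_mirs) == 0 || length(young_mirs) == 0) {
    stop("need at least one ancient and one young miRNA family")
  }

  for (g in seq_len(n_groups)) {
    m <- sizes[g]
    members <- gene_ids[gi + seq_len(m)]
    gi <- gi + m
    gid <- sprintf("GRP%04d", g)
    anc <- sample(ancient_mirs, 1)
    minlen <- min(nchar(tx[members]))
    pos <- sample(minlen - L + 1L, 1)
    score <- sample(config$site_score_dist$score, 1,
                    prob = config$site_score_dist$prob)
    window <- .plant_window(mirnas_df$seq[anc], score)
    for (mem in members) tx[[mem]] <- .splice_in(tx[[mem]], window, pos)

    u_loss <- runif(1); u_gain <- runif(1)
    mech <- "none"; verdict <- "same"
    lost_in <- NA_character_; gained_in <- NA_character_
    gain_mir <- NA_integer_
    member_sites <- data.frame(
      group_id = gid, gene_id = members, mirna_id = mirnas_df$id[anc],
      family = mirnas_df$family[anc], start = pos, end = pos + L - 1L,
      score = score, status = "planted"
    )
    if (u_loss < config$p_site_loss) {
      mech <- "loss"; verdict <- "divergent"
      lost_in <- sample(members, 1)
      dam <- .ablate_window(mirnas_df$seq[anc], window)
      tx[[lost_in]] <- .splice_in(tx[[lost_in]], dam, pos)
      row <- member_sites$gene_id == lost_in
      member_sites$status[row] <- "ablated"
      member_sites$score[row] <- score_duplex(mirnas_df$seq[anc], dam,
                                              scan_profile("plain", Inf))
    } else if (u_gain < config$p_young_gain) {
      mech <- "young_gain"; verdict <- "divergent"
      gained_in <- sample(members, 1)
      gain_mir <- sample(young_mirs, 1)
      gscore <- sample(config$site_score_dist$score, 1,
                       prob = config$site_score_dist$prob)
      gwin <- .plant_window(mirnas_df$seq[gain_mir], gscore)
      # place the gained site away from the ancestral one
      glen <- nchar(tx[[gained_in]])
      repeat {
        gpos <- sample(glen - L + 1L, 1)
        if (gpos + L - 1L < pos || gpos > pos + L - 1L) break
      }
      tx[[gained_in]] <- .splice_in(tx[[gained_in]], gwin, gpos)
      member_sites <- rbind(member_sites, data.frame(
        group_id = gid, gene_id = gained_in, mirna_id = mirnas_df$id[gain_mir],
        family = mirnas_df$family[gain_mir], start = gpos, end = gpos + L - 1L,
        score = gscore, status = "gained"
      ))
    }
    site_rows[[g]] <- member_sites
    group_rows[[g]] <- data.frame(
      group_id = gid, gene_a = members[1], gene_b = members[2],
      gene_c = if (m == 3) members[3] else NA_character_,
      class = classes[g]
    )
    truth_groups[[g]] <- data.frame(
      group_id = gid, class = classes[g], size = m, verdict = verdict,
      mechanism = mech, lost_in = lost_in, gained_in = gained_in,
      anc_family = mirnas_df$family[anc],
      gain_family = if (is.na(gain_mir)) NA_character_
                    else mirnas_df$family[gain_mir]
    )
    # reciprocal similarity hits among members
    pairs <- t(utils::combn(members, 2))
    hit_rows[[g]] <- data.frame(
      query_id = c(pairs[, 1], pairs[, 2]),
      subject_id = c(pairs[, 2], pairs[, 1]),
      evalue = 1e-50, query_coverage = 0.9, bitscore = 500
    )
  }

  singles <- gene_ids[(sum(sizes) + 1):n_genes]
  hits <- rbind(
    do.call(rbind, hit_rows),
    data.frame(query_id = gene_ids, subject_id = gene_ids, evalue = 0,
               query_coverage = 1, bitscore = 1000)
  )
  hits <- similarity_hits(hits$query_id, hits$subject_id, hits$evalue,
                          hits$query_coverage, hits$bitscore)

  # --- homolog hit table consistent with true ages ---
  hh <- lapply(seq_len(config$n_mirnas), function(i) {
    rows <- data.frame(mirna_id = mirnas_df$id[i],
                       species = "Arabidopsis thaliana",
                       evalue = 1e-30, coverage = 1)
    if (runif(1) < 0.5) {
      rows <- rbind(rows, data.frame(mirna_id = mirnas_df$id[i],
                                     species = "Arabidopsis lyrata",
                                     evalue = 1e-25, coverage = 0.95))
    }
    outg <- setdiff(default_species_panel(),
                    c("Arabidopsis thaliana", "Arabidopsis lyrata"))
    if (mirnas_df$age[i] == "ancient") {
      sp <- sample(outg, sample(3, 1))
      rows <- rbind(rows, data.frame(mirna_id = mirnas_df$id[i], species = sp,
                                     evalue = 1e-20, coverage = 0.8))
    } else if (runif(1) < 0.3) {
      # young miRNAs may still have weak, non-qualifying outgroup hits
      rows <- rbind(rows, data.frame(mirna_id = mirnas_df$id[i],
                                     species = sample(outg, 1),
                                     evalue = 1e-4, coverage = 0.6))
    }
    rows
  })
  homolog_hits <- do.call(rbind, hh)

  # --- expression matrix coupled to verdicts ---
  truth_g <- do.call(rbind, truth_groups)
  expr <- matrix(NA_real_, n_genes, config$n_conditions,
                 dimnames = list(gene_ids,
                                 sprintf("cond%02d", seq_len(config$n_conditions))))
  gi <- 0L
  for (g in seq_len(n_groups)) {
    m <- sizes[g]
    rho <- if (truth_g$verdict[g] == "divergent") config$rho_div else config$rho_same
    expr[gi + seq_len(m), ] <- .expr_rows(m, config$n_conditions, rho)
    gi <- gi + m
  }
  for (s in seq_along(singles)) {
    expr[sum(sizes) + s, ] <- .expr_rows(1, config$n_conditions, 0)
  }

  truth_sites <- do.call(rbind, site_rows)
  structure(list(
    mirnas = mirnas_df,
    mirna_seqs = setNames(mirnas_df$seq, mirnas_df$id),
    transcripts = tx,
    hits = hits,
    groups = do.call(rbind, group_rows),
    homolog_hits = homolog_hits,
    expression = expr,
    truth = list(
      groups = truth_g,
      sites = truth_sites,
      mirna_age = data.frame(mirna_id = mirnas_df$id,
                             family = mirnas_df$family, age = mirnas_df$age),
      gene_status = data.frame(
        gene_id = gene_ids,
        status = c(rep("duplicate", sum(sizes)),
                   rep("singleton", config$n_singletons)))
    ),
    config = config
  ), class = "synth_bundle")
}

#' Write a synthetic bundle to disk as plain-text files
#'
#' Emits `mirnas.fa`, `transcripts.fa`, `similarity_hits.tsv`,
#' `paralog_groups.tsv`, `mirna_homolog_hits.tsv`, `expression.tsv`, truth
#' tables and a `MANIFEST.tsv` describing each file.
#'
#' @param bundle a [generate_dataset()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "synth_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wtsv <- function(x, f) {
    write.table(x, file.path(dir, f), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  write_fasta(bundle$mirna_seqs, file.path(dir, "mirnas.fa"))
  write_fasta(bundle$transcripts, file.path(dir, "transcripts.fa"))
  wtsv(bundle$hits, "similarity_hits.tsv")
  wtsv(bundle$groups, "paralog_groups.tsv")
  wtsv(bundle$homolog_hits, "mirna_homolog_hits.tsv")
  expr <- data.frame(gene_id = rownames(bundle$expression), bundle$expression,
                     check.names = FALSE)
  wtsv(expr, "expression.tsv")
  wtsv(bundle$truth$groups, "truth_groups.tsv")
  wtsv(bundle$truth$sites, "truth_sites.tsv")
  wtsv(bundle$truth$mirna_age, "truth_mirna_age.tsv")
  wtsv(bundle$truth$gene_status, "truth_gene_status.tsv")
  manifest <- data.frame(
    file = c("mirnas.fa", "transcripts.fa", "similarity_hits.tsv",
             "paralog_groups.tsv", "mirna_homolog_hits.tsv", "expression.tsv",
             "truth_groups.tsv", "truth_sites.tsv", "truth_mirna_age.tsv",
             "truth_gene_status.tsv"),
    description = c("mature miRNA sequences (RNA FASTA)",
                    "transcript sequences (RNA FASTA)",
                    "all-vs-all similarity hits",
                    "labeled paralog pairs/triplets",
                    "cross-species miRNA homolog hits",
                    "normalized expression matrix (genes x conditions)",
                    "ground truth: group verdicts and mechanisms",
                    "ground truth: planted/ablated/gained sites",
                    "ground truth: miRNA ages",
                    "ground truth: duplicate/singleton status"),
    seed = bundle$config$seed
  )
  wtsv(manifest, "MANIFEST.tsv")
  invisible(dir)
}

#' Verify a bundle's ground truth by re-scanning its sequences
#'
#' Every planted or gained site must be recovered by [scan_transcript()]
#' at its recorded coordinates and plain score; every ablated site must
#' exceed the cutoff of every profile in `rule`.
#'
#' @param bundle a [generate_dataset()] result.
#' @param rule the [consensus_rule()] whose profiles the ablated sites must
#'   escape.
#' @return list with `ok` (logical) and `failures` (data.frame of
#'   per-site diffs, empty when `ok`).
#' @export
verify_truth <- function(bundle, rule = consensus_rule()) {
  stopifnot(inherits(bundle, "synth_bundle"))
  plain <- scan_profile("plain", 3)
  sites <- bundle$truth$sites
  mir_seq <- setNames(bundle$mirnas$seq, bundle$mirnas$id)
  fails <- list()
  for (i in seq_len(nrow(sites))) {
    s <- sites[i, ]
    txseq <- bundle$transcripts[[s$gene_id]]
    window <- substr(txseq, s$start, s$end)
    if (nchar(window) != s$end - s$start + 1) {
      fails[[length(fails) + 1]] <- cbind(s, observed_score = NA_real_)
      next
    }
    if (s$status %in% c("planted", "gained")) {
      sc <- score_duplex(mir_seq[[s$mirna_id]], window, plain)
      hits <- scan_transcript(
        mirna(s$mirna_id, mir_seq[[s$mirna_id]]),
        transcript(s$gene_id, txseq), plain
      )
      found <- any(hits$start == s$start & abs(hits$score - s$score) < 1e-9)
      if (!found || abs(sc - s$score) > 1e-9) {
        fails[[length(fails) + 1]] <- cbind(s, observed_score = sc)
      }
    } else {  # ablated
      esc <- vapply(rule$profiles, function(p) {
        score_duplex(mir_seq[[s$mirna_id]], window, p) > p$cutoff
      }, logical(1))
      if (!all(esc)) {
        fails[[length(fails) + 1]] <- cbind(s, observed_score = NA_real_)
      }
    }
  }
  failures <- if (length(fails)) do.call(rbind, fails) else sites[0, ]
  list(ok = length(fails) == 0, failures = failures)
}
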