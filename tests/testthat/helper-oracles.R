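# Independent brute-force oracles, coded separately from the package
# implementation (different pairing table representation, different genetic
# code source, exhaustive enumeration) so that agreement is meaningful.

RNA4 <- c("A", "C", "G", "U")

random_rna <- function(len, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(RNA4, len, replace = TRUE, prob = p), collapse = "")
}

# a binding window for `mirna_seq` carrying n_mm out-of-seed mismatches
# (plain score = n_mm), built from exported functions only
.damaged_site <- function(mirna_seq, n_mm = 0) {
  L <- nchar(mirna_seq)
  mb <- strsplit(mirna_seq, "")[[1]]
  wb <- strsplit(unname(reverse_complement(mirna_seq)), "")[[1]]
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  wob <- c(G = "U", U = "G")
  pos <- sample(c(1, 14:L), n_mm)
  for (i in pos) {
    bad <- setdiff(RNA4, c(comp[[mb[i]]], wob[mb[i]]))
    bad <- bad[!is.na(bad)]
    wb[L + 1 - i] <- sample(bad, 1)
  }
  paste(wb, collapse = "")
}

# --- duplex scoring oracle: per-pair string lookup -----------------------
oracle_pair_penalty <- function(mb, wb, wobble, mismatch) {
  key <- paste0(mb, wb)
  if (key %in% c("AU", "UA", "GC", "CG")) return(0)
  if (key %in% c("GU", "UG")) return(wobble)
  mismatch
}

oracle_score <- function(mseq, wseq, profile) {
  m <- strsplit(mseq, "")[[1]]
  w <- strsplit(wseq, "")[[1]]
  L <- length(m)
  total <- 0
  for (i in seq_len(L)) {
    wp <- profile$wobble_penalty
    mp <- profile$mismatch_penalty
    if (!is.null(profile$seed_range) && i %in% profile$seed_range) {
      wp <- if (!is.null(profile$seed_wobble_penalty)) {
        profile$seed_wobble_penalty
      } else wp * profile$seed_multiplier
      mp <- if (!is.null(profile$seed_mismatch_penalty)) {
        profile$seed_mismatch_penalty
      } else mp * profile$seed_multiplier
    }
    total <- total + oracle_pair_penalty(m[i], w[L + 1 - i], wp, mp)
  }
  total
}

oracle_scan <- function(mseq, txseq, profile) {
  L <- nchar(mseq)
  n <- nchar(txseq) - L + 1
  starts <- integer(0)
  scores <- numeric(0)
  if (n >= 1) {
    for (s in seq_len(n)) {
      sc <- oracle_score(mseq, substr(txseq, s, s + L - 1), profile)
      if (sc <= profile$cutoff) {
        starts <- c(starts, s)
        scores <- c(scores, sc)
      }
    }
  }
  data.frame(start = starts, end = starts + L - 1L, score = scores)
}

# --- NG86 oracle: seqinr genetic code, exhaustive pathway recursion ------
oracle_aa <- function(codon) {
  seqinr::translate(seqinr::s2c(chartr("U", "T", codon)))
}

oracle_syn_sites <- function(codon) {
  b <- strsplit(codon, "")[[1]]
  aa <- oracle_aa(codon)
  tot <- 0
  for (k in 1:3) {
    for (nb in setdiff(RNA4, b[k])) {
      b2 <- b
      b2[k] <- nb
      if (oracle_aa(paste(b2, collapse = "")) == aa) tot <- tot + 1 / 3
    }
  }
  tot
}

oracle_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  do.call(c, lapply(seq_along(v), function(i) {
    lapply(oracle_perms(v[-i]), function(p) c(v[i], p))
  }))
}

oracle_path_counts <- function(c1, c2) {
  b1 <- strsplit(c1, "")[[1]]
  b2 <- strsplit(c2, "")[[1]]
  pos <- which(b1 != b2)
  if (length(pos) == 0) return(c(0, 0))
  walks <- lapply(oracle_perms(pos), function(ord) {
    cur <- b1
    sy <- 0; ns <- 0; blocked <- FALSE
    for (k in ord) {
      a1 <- oracle_aa(paste(cur, collapse = ""))
      cur[k] <- b2[k]
      nxt <- paste(cur, collapse = "")
      a2 <- oracle_aa(nxt)
      if (a2 == "*" && nxt != c2) blocked <- TRUE
      if (a1 == a2) sy <- sy + 1 else ns <- ns + 1
    }
    list(sy = sy, ns = ns, blocked = blocked)
  })
  ok <- Filter(function(w) !w$blocked, walks)
  if (length(ok) == 0) ok <- walks
  c(mean(vapply(ok, `[[`, numeric(1), "sy")),
    mean(vapply(ok, `[[`, numeric(1), "ns")))
}

oracle_ng86 <- function(cod_a, cod_b) {
  S <- (sum(vapply(cod_a, oracle_syn_sites, numeric(1))) +
          sum(vapply(cod_b, oracle_syn_sites, numeric(1)))) / 2
  N <- 3 * length(cod_a) - S
  d <- vapply(seq_along(cod_a), function(i) {
    oracle_path_counts(cod_a[i], cod_b[i])
  }, numeric(2))
  Sd <- sum(d[1, ]); Nd <- sum(d[2, ])
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  list(ka = jc(Nd / N), ks = jc(Sd / S), S = S, N = N, Sd = Sd, Nd = Nd)
}

# random in-frame codon pair without stop codons, moderate divergence
random_codon_pair <- function(n_codons, p_mut = 0.08) {
  is_stop <- function(codon) oracle_aa(codon) == "*"
  draw_codon <- function() {
    repeat {
      codon <- paste(sample(RNA4, 3, replace = TRUE), collapse = "")
      if (!is_stop(codon)) return(codon)
    }
  }
  a <- vapply(seq_len(n_codons), function(i) draw_codon(), character(1))
  b <- vapply(a, function(codon) {
    repeat {
      bb <- strsplit(codon, "")[[1]]
      for (k in 1:3) {
        if (runif(1) < p_mut) bb[k] <- sample(RNA4, 1)
      }
      cand <- paste(bb, collapse = "")
      if (!is_stop(cand)) return(cand)
    }
  }, character(1))
  list(a = a, b = b)
}

# --- Fitch oracle: exhaustive minimization over internal labelings -------
oracle_min_changes <- function(tree, states) {
  ntip <- length(tree$tip.label)
  edge <- tree$edge
  grid <- expand.grid(rep(list(0:1), tree$Nnode))
  tip_states <- as.numeric(states[tree$tip.label])
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    lab <- c(tip_states, as.numeric(grid[r, ]))
    best <- min(best, sum(lab[edge[, 1]] != lab[edge[, 2]]))
  }
  best
}

# count changes implied by a full labeling (to validate returned labelings)
count_changes <- function(tree, labeling) {
  sum(labeling[tree$edge[, 1]] != labeling[tree$edge[, 2]])
}
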