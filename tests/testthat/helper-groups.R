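# build classified paralog groups with prescribed target-set patterns, used
# to reconstruct published-table-shaped cohorts

.gid_counter <- local({
  i <- 0L
  function() {
    i <<- i + 1L
    sprintf("HG%05d", i)
  }
})

# pattern: list of character vectors, one per member gene
make_group <- function(pattern, dup_class = "WGD") {
  genes <- paste0("g", seq_along(pattern), "_", .gid_counter())
  names(pattern) <- genes
  classify_pair(paralog_group(genes, dup_class = dup_class,
                              target_sets = pattern))
}

# n copies of the same pattern
make_groups <- function(n, pattern, dup_class = "WGD") {
  lapply(seq_len(max(n, 0)), function(i) make_group(pattern, dup_class))
}

same_pair <- function(n, dup_class = "WGD") {
  make_groups(n, list(c("famA"), c("famA")), dup_class)
}

asym_pair <- function(n, dup_class = "WGD") {
  make_groups(n, list(c("famA"), character(0)), dup_class)
}

diff_pair <- function(n, dup_class = "WGD") {
  make_groups(n, list(c("famA"), c("famB")), dup_class)
}
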