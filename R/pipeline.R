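# End-to-end orchestration: scan -> catalog -> divergence classification ->
# miRNA age attribution -> expression and enrichment statistics. Inputs are
# either a synthetic bundle or the corresponding files read individually;
# re-running on identical inputs gives identical results (no randomness in
# the pipeline itself).

#' Read a dataset bundle from a directory written by [write_bundle()]
#'
#' @param dir directory holding the bundle files.
#' @return list shaped like a [generate_dataset()] bundle (without truth if
#'   the truth tables are absent).
#' @export
read_bundle <- function(dir) {
  rtsv <- function(f) read.table(file.path(dir, f), sep = "\t", header = TRUE,
                                 stringsAsFactors = FALSE,
                                 na.strings = c("NA", ""))
  mir <- read_fasta(file.path(dir, "mirnas.fa"), "rna")
  tx <- read_fasta(file.path(dir, "transcripts.fa"), "rna")
  hits <- rtsv("similarity_hits.tsv")
  expr_df <- rtsv("expression.tsv")
  expr <- as.matrix(expr_df[, -1, drop = FALSE])
  rownames(expr) <- expr_df$gene_id
  out <- list(
    mirna_seqs = setNames(as.character(mir), names(mir)),
    transcripts = setNames(as.character(tx), names(tx)),
    hits = similarity_hits(hits$query_id, hits$subject_id, hits$evalue,
                           hits$query_coverage, hits$bitscore),
    groups = rtsv("paralog_groups.tsv"),
    homolog_hits = rtsv("mirna_homolog_hits.tsv"),
    expression = expr
  )
  truth_f <- file.path(dir, "truth_groups.tsv")
  if (file.exists(truth_f)) {
    out$truth <- list(groups = rtsv("truth_groups.tsv"),
                      sites = rtsv("truth_sites.tsv"),
                      mirna_age = rtsv("truth_mirna_age.tsv"),
                      gene_status = rtsv("truth_gene_status.tsv"))
  }
  class(out) <- "synth_bundle"
  out
}

.bundle_mirnas <- function(bundle) {
  as_mirnas(bundle$mirna_seqs)
}

#' Build paralog groups from a group label table and target sets
#'
#' @param group_table data.frame with columns `gene_a`, `gene_b`, optional
#'   `gene_c` (NA for pairs), `class`, optional `group_id`.
#' @param sets named list of per-gene family sets (see [target_sets()]).
#' @return list of [paralog_group()] objects.
#' @export
groups_from_table <- function(group_table, sets) {
  lapply(seq_len(nrow(group_table)), function(i) {
    row <- group_table[i, ]
    genes <- c(row$gene_a, row$gene_b,
               if ("gene_c" %in% names(row)) row$gene_c else NA)
    genes <- genes[!is.na(genes)]
    paralog_group(genes, dup_class = row$class, target_sets = sets[genes],
                  group_id = if ("group_id" %in% names(row)) row$group_id else NULL)
  })
}

#' Run the full divergence analysis on a dataset bundle
#'
#' Stages: consensus target scan, duplicate/singleton catalog and
#' enrichment test, same/divergent classification with class and
#' target-count summaries, young/ancient age attribution, and the
#' expression-correlation contrast between same and divergent groups.
#'
#' @param bundle a [generate_dataset()] / [read_bundle()] bundle.
#' @param rule the [consensus_rule()] used for scanning.
#' @param coordinate_aware compare binding sites as (family, position-bin)
#'   pairs instead of family sets.
#' @param yates continuity correction for the enrichment chi-square.
#' @return list of class `pipeline_report` with elements `target_table`,
#'   `catalog`, `enrichment` (table + test or a note), `groups`, `summary`,
#'   `ages`, `attribution`, `expression` (per-group correlations + group
#'   contrast or a note) and `meta`.
#' @export
run_pipeline <- function(bundle, rule = consensus_rule(),
                         coordinate_aware = FALSE, yates = FALSE) {
  mirnas <- .bundle_mirnas(bundle)
  transcripts <- as_transcripts(bundle$transcripts)
  genes <- names(bundle$transcripts)

  tt <- target_table(mirnas, transcripts, rule)
  sets <- target_sets(tt, genes, coordinate_aware = coordinate_aware)

  catalog <- classify_genes(bundle$hits, genes)
  enr_tab <- enrichment_table(catalog, tt$target_genes)
  enrichment <- list(table = enr_tab)
  if (any(rowSums(enr_tab) == 0) || any(colSums(enr_tab) == 0)) {
    enrichment$note <- "test skipped: zero marginal"
  } else {
    enrichment$test <- chi_square_2x2(enr_tab, yates = yates)
  }

  groups <- classify_groups(groups_from_table(bundle$groups, sets))
  summary <- summarize_groups(groups)

  ages_df <- classify_mirna_age(bundle$homolog_hits,
                                mirna_ids = vapply(mirnas, `[[`, "", "id"))
  # attribution works at the family level: a family is young when any of
  # its member miRNAs is young
  fam_of <- vapply(mirnas, `[[`, "", "family")
  age_of <- setNames(ages_df$age[match(names(fam_of), ages_df$mirna_id)],
                     names(fam_of))
  fam_age <- vapply(split(age_of, fam_of), function(a) {
    if (any(a == "young")) "young" else "ancient"
  }, character(1))
  if (coordinate_aware) {
    keys <- unique(unlist(lapply(groups, function(g) unlist(g$target_sets))))
    fam_age <- c(fam_age, setNames(fam_age[sub("@.*$", "", keys)], keys))
  }
  attribution <- attribute_divergence_age(groups, fam_age)

  verdicts <- vapply(groups, `[[`, "", "verdict")
  r_by_group <- vapply(seq_along(groups), function(i) {
    g <- groups[[i]]
    if (length(g$genes) == 2) {
      suppressWarnings(pearson_r(bundle$expression[g$genes[1], ],
                                 bundle$expression[g$genes[2], ]))
    } else {
      combs <- utils::combn(g$genes, 2)
      mean(vapply(seq_len(ncol(combs)), function(k) {
        suppressWarnings(pearson_r(bundle$expression[combs[1, k], ],
                                   bundle$expression[combs[2, k], ]))
      }, numeric(1)))
    }
  }, numeric(1))
  expression <- list(
    correlations = data.frame(
      group_id = vapply(groups, `[[`, "", "group_id"),
      verdict = verdicts, r = r_by_group)
  )
  r_same <- r_by_group[verdicts == "same"]
  r_div <- r_by_group[verdicts == "divergent"]
  if (length(r_same) && length(r_div)) {
    expression$contrast <- compare_correlation_groups(r_same, r_div)
  } else {
    expression$note <- "contrast skipped: a verdict group is empty"
  }

  structure(list(
    target_table = tt, catalog = catalog, enrichment = enrichment,
    groups = groups, summary = summary, ages = ages_df,
    attribution = attribution, expression = expression,
    meta = list(
      k = rule$k, n_profiles = length(rule$profiles),
      coordinate_aware = coordinate_aware,
      divergence_definition = "miRNA family set inequality",
      kaks_method = "NG86+JC (not run without CDS input)"
    )
  ), class = "pipeline_report")
}

#' Write the table-shaped pipeline outputs to a directory
#'
#' Emits `sites.tsv`, `interactions.tsv`, the by-class and by-target-count
#' summaries, the per-group verdicts and a JSON-like stats text file.
#'
#' @param report a [run_pipeline()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "pipeline_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wtsv <- function(x, f) write.table(x, file.path(dir, f), sep = "\t",
                                     quote = FALSE, row.names = FALSE)
  wtsv(report$target_table$sites, "sites.tsv")
  wtsv(report$target_table$interactions, "interactions.tsv")
  wtsv(report$summary$by_class, "summary_by_class.tsv")
  if (nrow(report$summary$by_target_count)) {
    wtsv(report$summary$by_target_count, "summary_by_target_count.tsv")
  }
  wtsv(report$summary$groups, "group_verdicts.tsv")
  wtsv(report$ages, "mirna_ages.tsv")
  wtsv(report$expression$correlations, "expression_correlations.tsv")
  stats <- c(
    sprintf("n_interactions\t%d", report$target_table$summary$n_interactions),
    sprintf("n_target_genes\t%d", report$target_table$summary$n_target_genes),
    sprintf("mean_sites_per_target\t%.4f",
            report$target_table$summary$mean_sites_per_target),
    sprintf("pct_divergent_young\t%s", report$attribution$pct_divergent_young),
    if (!is.null(report$enrichment$test)) {
      sprintf("enrichment_p\t%.6g", report$enrichment$test$p_value)
    },
    if (!is.null(report$expression$contrast)) {
      sprintf("expression_contrast_p\t%.6g", report$expression$contrast$p_value)
    }
  )
  writeLines(stats, file.path(dir, "stats.tsv"))
  invisible(dir)
}
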