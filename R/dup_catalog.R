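# Duplicate/singleton cataloguing from all-vs-all protein similarity hits.
# A gene is a duplicate when it has at least one nonself hit with E < 1e-10
# and query coverage > 50%; a singleton when it has no nonself hit with
# E < 1e-3. Genes caught between the two rules form an explicit
# "unclassified" class and are excluded from enrichment testing. Coverage is
# aligned query length / query length, evaluated with the gene as query.

#' Read similarity hits from 12-column tabular format
#'
#' Expects the standard 12-column tabular hit layout (query, subject,
#' identity, length, mismatches, gapopens, qstart, qend, sstart, send,
#' evalue, bitscore) with either a 13th `qlen` column or a separate
#' gene-length table to derive query coverage.
#'
#' @param path path to the tab-separated hit file (no header).
#' @param gene_lengths optional named vector of query lengths, required when
#'   the file has no 13th column.
#' @return data.frame with columns `query_id`, `subject_id`, `evalue`,
#'   `query_coverage`, `bitscore`.
#' @export
read_similarity_hits <- function(path, gene_lengths = NULL) {
  tab <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 12) stop("expected >= 12 tab-separated columns, got ", ncol(tab))
  qlen <- if (ncol(tab) >= 13) {
    as.numeric(tab[[13]])
  } else {
    if (is.null(gene_lengths)) {
      stop("no qlen column and no gene_lengths table; cannot compute coverage")
    }
    missing <- setdiff(unique(tab[[1]]), names(gene_lengths))
    if (length(missing)) stop("no length for query gene(s): ",
                              paste(utils::head(missing, 5), collapse = ", "))
    as.numeric(gene_lengths[tab[[1]]])
  }
  similarity_hits(tab[[1]], tab[[2]], as.numeric(tab[[11]]),
                  (abs(tab[[8]] - tab[[7]]) + 1) / qlen,
                  as.numeric(tab[[12]]))
}

#' Construct a similarity-hit table
#'
#' @param query_id,subject_id gene identifiers.
#' @param evalue E values (>= 0).
#' @param query_coverage aligned fraction of the query length, in `[0, 1]`.
#' @param bitscore optional bit scores.
#' @return data.frame of hits; self-hits are retained but flagged in the
#'   `self` column.
#' @export
similarity_hits <- function(query_id, subject_id, evalue, query_coverage,
                            bitscore = NA_real_) {
  stopifnot(all(evalue >= 0), all(query_coverage >= 0),
            all(query_coverage <= 1 + 1e-9))
  bitscore <- rep_len(bitscore, length(query_id))
  data.frame(query_id = as.character(query_id),
             subject_id = as.character(subject_id),
             evalue = evalue, query_coverage = pmin(query_coverage, 1),
             bitscore = bitscore,
             self = as.character(query_id) == as.character(subject_id))
}

#' Classify genes into duplicates, singletons and unclassified
#'
#' @param hits a [similarity_hits()] data.frame.
#' @param genes character vector of all gene ids in the universe.
#' @param dup_evalue duplicate rule: E value must be strictly below this.
#' @param dup_cov duplicate rule: query coverage must be strictly above this.
#' @param singleton_evalue singleton rule: a gene is a singleton when none of
#'   its nonself hits has E strictly below this.
#' @return object of class `gene_catalog` holding `assignment` (data.frame
#'   `gene_id`, `class`) and the thresholds used.
#' @export
classify_genes <- function(hits, genes, dup_evalue = 1e-10, dup_cov = 0.5,
                           singleton_evalue = 1e-3) {
  stopifnot(length(genes) > 0, !anyDuplicated(genes))
  unknown <- setdiff(unique(c(hits$query_id, hits$subject_id)), genes)
  if (length(unknown)) {
    stop("hit table names gene(s) absent from the gene list: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  ns <- hits[hits$query_id != hits$subject_id, , drop = FALSE]
  dup_genes <- unique(ns$query_id[ns$evalue < dup_evalue &
                                    ns$query_coverage > dup_cov])
  weak_genes <- unique(ns$query_id[ns$evalue < singleton_evalue])
  cls <- ifelse(genes %in% dup_genes, "duplicate",
                ifelse(genes %in% weak_genes, "unclassified", "singleton"))
  gene_catalog(data.frame(gene_id = genes, class = cls),
               thresholds = list(dup_evalue = dup_evalue, dup_cov = dup_cov,
                                 singleton_evalue = singleton_evalue))
}

#' Construct a gene catalog from an explicit assignment
#'
#' @param assignment data.frame with columns `gene_id` and `class`
#'   (`duplicate` / `singleton` / `unclassified`).
#' @param pair_labels optional data.frame of labeled paralog groups
#'   (`gene_a`, `gene_b`, optional `gene_c`, `class`).
#' @param thresholds metadata list recorded with the catalog.
#' @return object of class `gene_catalog`.
#' @export
gene_catalog <- function(assignment, pair_labels = NULL, thresholds = NULL) {
  stopifnot(all(c("gene_id", "class") %in% names(assignment)),
            !anyDuplicated(assignment$gene_id),
            all(assignment$class %in% c("duplicate", "singleton", "unclassified")))
  if (!is.null(pair_labels)) {
    members <- unlist(pair_labels[intersect(c("gene_a", "gene_b", "gene_c"),
                                            names(pair_labels))])
    members <- members[!is.na(members) & nzchar(members)]
    if (!all(members %in% assignment$gene_id)) {
      stop("pair labels reference genes absent from the catalog")
    }
  }
  structure(list(assignment = assignment, pair_labels = pair_labels,
                 thresholds = thresholds, coverage_definition = "query"),
            class = "gene_catalog")
}

#' 2x2 target-enrichment counts for duplicates versus singletons
#'
#' Unclassified genes are excluded; target ids not present in the catalog
#' are dropped with a warning.
#'
#' @param catalog a [gene_catalog()].
#' @param targets character vector of miRNA target gene ids.
#' @return 2x2 integer matrix with rows `duplicate`/`singleton` and columns
#'   `target`/`non_target`.
#' @export
enrichment_table <- function(catalog, targets) {
  stopifnot(inherits(catalog, "gene_catalog"))
  asg <- catalog$assignment
  if (nrow(asg) == 0) stop("empty catalog")
  drop <- setdiff(targets, asg$gene_id)
  if (length(drop)) {
    warning(length(drop), " target gene(s) absent from the catalog were dropped")
    targets <- intersect(targets, asg$gene_id)
  }
  asg <- asg[asg$class != "unclassified", , drop = FALSE]
  is_target <- asg$gene_id %in% targets
  m <- matrix(
    c(sum(asg$class == "duplicate" & is_target),
      sum(asg$class == "duplicate" & !is_target),
      sum(asg$class == "singleton" & is_target),
      sum(asg$class == "singleton" & !is_target)),
    nrow = 2, byrow = TRUE,
    dimnames = list(c("duplicate", "singleton"), c("target", "non_target"))
  )
  storage.mode(m) <- "integer"
  m
}

#' Read labeled paralog groups from TSV
#'
#' @param path TSV with header columns `gene_a`, `gene_b`, optional `gene_c`
#'   (empty/NA for pairs), and `class` in `WGD`/`TD`/`other`/`triplet`.
#' @return data.frame of group labels.
#' @export
read_pair_labels <- function(path) {
  tab <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    na.strings = c("NA", ""))
  stopifnot(all(c("gene_a", "gene_b", "class") %in% names(tab)))
  if (!all(tab$class %in% c("WGD", "TD", "other", "triplet"))) {
    stop("pair class must be one of WGD, TD, other, triplet")
  }
  tab
}
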