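# Same-versus-divergent classification of paralog groups. A group (pair or
# triplet) is "same" when every member is targeted and all members carry
# identical miRNA family sets; it is "divergent" when at least one member is
# targeted but the family sets differ (including the case where a member has
# no site at all); it is "not_applicable" when no member is targeted.
# Comparison is at the level of miRNA family sets, not site coordinates: the
# biological question is which miRNAs regulate each paralog. A
# coordinate-aware mode additionally bins site start positions so that the
# same family bound at distant positions counts as divergent.

#' Construct a paralog group
#'
#' @param genes character vector of 2 or 3 gene ids.
#' @param dup_class duplication class: `WGD`, `TD`, `other` or `triplet`.
#' @param target_sets named list (one entry per gene) of character vectors of
#'   miRNA family keys; empty vector = untargeted gene.
#' @param group_id optional identifier.
#' @return object of class `paralog_group`.
#' @export
paralog_group <- function(genes, dup_class = c("WGD", "TD", "other", "triplet"),
                          target_sets, group_id = NULL) {
  dup_class <- match.arg(dup_class)
  if (!length(genes) %in% c(2L, 3L)) {
    stop("a paralog group has 2 or 3 genes, got ", length(genes))
  }
  stopifnot(!anyDuplicated(genes))
  if (is.null(names(target_sets))) names(target_sets) <- genes
  if (!setequal(names(target_sets), genes)) {
    stop("target_sets must be keyed by the group's gene ids")
  }
  target_sets <- lapply(target_sets[genes], function(s) sort(unique(as.character(s))))
  structure(list(group_id = group_id %||% paste(genes, collapse = "|"),
                 genes = genes, dup_class = dup_class,
                 target_sets = target_sets,
                 verdict = NA_character_, subtype = NA_character_),
            class = "paralog_group")
}

#' Classify a paralog group as same or divergent
#'
#' Verdicts: `not_applicable` when no member is targeted; `same` when all
#' members are targeted by identical family sets; `divergent` otherwise.
#' Subtypes: `asymmetric` (divergent with at least one untargeted member),
#' `different_mirnas` (divergent, all members targeted), `all_same`,
#' `none`. The call is invariant under permutation of member genes.
#'
#' @param group a [paralog_group()].
#' @return the group with `verdict` and `subtype` filled in.
#' @export
classify_pair <- function(group) {
  stopifnot(inherits(group, "paralog_group"))
  sets <- group$target_sets
  nonempty <- lengths(sets) > 0
  if (!any(nonempty)) {
    group$verdict <- "not_applicable"
    group$subtype <- "none"
  } else if (all(nonempty) &&
             all(vapply(sets[-1], identical, logical(1), y = sets[[1]]))) {
    group$verdict <- "same"
    group$subtype <- "all_same"
  } else {
    group$verdict <- "divergent"
    group$subtype <- if (any(!nonempty)) "asymmetric" else "different_mirnas"
  }
  group
}

#' Classify a list of paralog groups
#'
#' @param groups list of [paralog_group()] objects.
#' @return list of classified groups.
#' @export
classify_groups <- function(groups) lapply(groups, classify_pair)

.group_df <- function(groups) {
  data.frame(
    group_id = vapply(groups, `[[`, "", "group_id"),
    dup_class = vapply(groups, `[[`, "", "dup_class"),
    size = vapply(groups, function(g) length(g$genes), integer(1)),
    n_targeted = vapply(groups, function(g) sum(lengths(g$target_sets) > 0),
                        integer(1)),
    verdict = vapply(groups, `[[`, "", "verdict"),
    subtype = vapply(groups, `[[`, "", "subtype")
  )
}

#' Summarize same/divergent verdicts by duplication class
#'
#' Produces the two table shapes used throughout the analysis: counts of
#' same/divergent groups per duplication class (plus a `Total` row) with
#' the percent divergent among targeted groups (round-half-up), and a
#' breakdown of pairs/triplets by how many members are targeted.
#'
#' @param groups list of classified [paralog_group()] objects.
#' @return list of class `group_summary` with elements `groups` (per-group
#'   data.frame), `by_class` and `by_target_count`.
#' @export
summarize_groups <- function(groups) {
  if (length(groups) == 0) {
    return(structure(list(groups = .group_df(list()),
                          by_class = data.frame(), by_target_count = data.frame()),
                     class = "group_summary"))
  }
  if (anyNA(vapply(groups, `[[`, "", "verdict"))) {
    stop("groups must be classified first (see classify_groups)")
  }
  df <- .group_df(groups)
  classes <- intersect(c("WGD", "TD", "other", "triplet"), unique(df$dup_class))
  tab <- function(sub) {
    n_same <- sum(sub$verdict == "same")
    n_div <- sum(sub$verdict == "divergent")
    data.frame(n_same = n_same, n_divergent = n_div, n_total = n_same + n_div,
               n_not_applicable = sum(sub$verdict == "not_applicable"),
               pct_divergent = pct_half_up(n_div, n_same + n_div))
  }
  by_class <- do.call(rbind, lapply(classes, function(cl) {
    cbind(dup_class = cl, tab(df[df$dup_class == cl, ]))
  }))
  by_class <- rbind(by_class, cbind(dup_class = "Total", tab(df)))
  rownames(by_class) <- NULL
  targeted <- df[df$verdict != "not_applicable", , drop = FALSE]
  if (nrow(targeted)) {
    targeted$category <- paste0(ifelse(targeted$size == 2, "pair_", "triplet_"),
                                targeted$n_targeted)
    cats <- c("pair_1", "pair_2", "triplet_1", "triplet_2", "triplet_3")
    cats <- cats[cats %in% targeted$category]
    by_tc <- do.call(rbind, lapply(c("same", "divergent"), function(v) {
      counts <- vapply(cats, function(ca) {
        sum(targeted$verdict == v & targeted$category == ca)
      }, integer(1))
      data.frame(verdict = v, t(counts), total = sum(counts),
                 check.names = FALSE)
    }))
    rownames(by_tc) <- NULL
  } else {
    by_tc <- data.frame()
  }
  structure(list(groups = df, by_class = by_class, by_target_count = by_tc),
            class = "group_summary")
}

#' Default cross-species panel for miRNA age classification
#'
#' The two *Arabidopsis* species form the ingroup; the rest is a
#' representative set of land-plant (plus two algal/basal) genomes commonly
#' used as outgroups. Both the panel and the ingroup are configurable in
#' [classify_mirna_age()].
#'
#' @return character vector of species names.
#' @export
default_species_panel <- function() {
  c("Arabidopsis thaliana", "Arabidopsis lyrata", "Capsella rubella",
    "Brassica rapa", "Thellungiella parvula", "Carica papaya",
    "Populus trichocarpa", "Ricinus communis", "Glycine max",
    "Medicago truncatula", "Cucumis sativus", "Vitis vinifera",
    "Solanum lycopersicum", "Solanum tuberosum", "Mimulus guttatus",
    "Aquilegia coerulea", "Oryza sativa", "Brachypodium distachyon",
    "Sorghum bicolor", "Zea mays", "Setaria italica", "Amborella trichopoda",
    "Selaginella moellendorffii", "Physcomitrella patens",
    "Chlamydomonas reinhardtii")
}

#' Classify miRNAs as young or ancient from cross-species homolog hits
#'
#' A miRNA is `young` when it has no qualifying homolog hit (E value
#' strictly below `evalue`, coverage strictly above `coverage`) in any
#' species outside the ingroup and is not annotated as having outgroup
#' homologs; otherwise it is `ancient`. miRNAs listed in `mirna_ids` but
#' absent from the hit table are young by the vacuous rule (with a message).
#'
#' @param hits data.frame with columns `mirna_id`, `species`, `evalue`,
#'   `coverage`.
#' @param mirna_ids ids to classify; defaults to those present in `hits`.
#' @param ingroup species whose hits never count against youth.
#' @param panel declared species panel; an unknown species string is an
#'   error.
#' @param evalue,coverage qualifying-hit thresholds.
#' @param annotation_override ids annotated as having outgroup homologs
#'   regardless of the hit table.
#' @return data.frame with columns `mirna_id`, `age`.
#' @export
classify_mirna_age <- function(hits, mirna_ids = NULL,
                               ingroup = c("Arabidopsis thaliana",
                                           "Arabidopsis lyrata"),
                               panel = default_species_panel(),
                               evalue = 1e-10, coverage = 0.5,
                               annotation_override = character()) {
  stopifnot(all(c("mirna_id", "species", "evalue", "coverage") %in% names(hits)))
  panel <- union(panel, ingroup)
  unknown <- setdiff(unique(hits$species), panel)
  if (length(unknown)) {
    stop("unknown species '", unknown[1], "'; declared panel: ",
         paste(panel, collapse = ", "))
  }
  mirna_ids <- mirna_ids %||% sort(unique(hits$mirna_id))
  missing <- setdiff(mirna_ids, hits$mirna_id)
  if (length(missing)) {
    message(length(missing), " miRNA(s) without any homolog hit row; ",
            "classified young by the vacuous rule")
  }
  qual <- hits[!(hits$species %in% ingroup) & hits$evalue < evalue &
                 hits$coverage > coverage, , drop = FALSE]
  ancient <- union(unique(qual$mirna_id), annotation_override)
  data.frame(mirna_id = mirna_ids,
             age = ifelse(mirna_ids %in% ancient, "ancient", "young"))
}

# families not shared by every member: the generalized symmetric difference
.divergence_families <- function(sets) {
  all_f <- unique(unlist(sets))
  shared <- all_f[vapply(all_f, function(f) {
    all(vapply(sets, function(s) f %in% s, logical(1)))
  }, logical(1))]
  setdiff(all_f, shared)
}

#' Attribute binding-site divergence to young versus ancient miRNAs
#'
#' For each divergent group, the miRNA families responsible for the
#' divergence are those in the symmetric difference of the members' target
#' sets (present in some members but not all); the group is
#' `young_attributed` when at least one of them is young, else
#' `ancient_only`. Groups with the `same` verdict are tallied separately by
#' whether any involved miRNA is young.
#'
#' @param groups list of classified [paralog_group()] objects.
#' @param ages data.frame from [classify_mirna_age()] or a named character
#'   vector, keyed by miRNA family key.
#' @return list of class `age_attribution` with a per-group data.frame and
#'   cohort fractions.
#' @export
attribute_divergence_age <- function(groups, ages) {
  if (is.data.frame(ages)) ages <- setNames(ages$age, ages$mirna_id)
  rows <- lapply(groups, function(g) {
    if (is.na(g$verdict)) stop("groups must be classified first")
    fams <- unique(unlist(g$target_sets))
    missing <- setdiff(fams, names(ages))
    if (length(missing)) {
      stop("no age for miRNA family '", missing[1], "'")
    }
    if (g$verdict == "divergent") {
      diff_f <- .divergence_families(g$target_sets)
      att <- if (any(ages[diff_f] == "young")) "young_attributed" else "ancient_only"
    } else if (g$verdict == "same") {
      att <- if (length(fams) && any(ages[fams] == "young"))
        "young_involved" else "ancient_only"
    } else {
      att <- NA_character_
    }
    data.frame(group_id = g$group_id, verdict = g$verdict, attribution = att)
  })
  df <- do.call(rbind, rows)
  div <- df[df$verdict == "divergent", , drop = FALSE]
  sam <- df[df$verdict == "same", , drop = FALSE]
  structure(list(
    groups = df,
    n_divergent = nrow(div),
    n_divergent_young = sum(div$attribution == "young_attributed"),
    pct_divergent_young = pct_half_up(sum(div$attribution == "young_attributed"),
                                      nrow(div)),
    n_same = nrow(sam),
    n_same_young = sum(sam$attribution == "young_involved"),
    pct_same_young = pct_half_up(sum(sam$attribution == "young_involved"),
                                 nrow(sam))
  ), class = "age_attribution")
}
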