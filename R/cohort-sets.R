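# Cohort comparison bookkeeping: all pairwise contrasts, the R+/S+
# duplicate-exclusion rule, and the disjoint Venn partition of up/down
# regulated miRNAs relative to the uninfected susceptible (S-) baseline.

#' All pairwise cohort and tissue comparisons
#'
#' Runs every cohort pair within each tissue (6 x 2) plus the fat-body vs
#' cuticle contrast within each cohort (4), 16 comparisons in total, and
#' tabulates differential-expression counts. Cohorts missing from the design
#' are reported with `NA` counts and a warning.
#'
#' @param x normalized log2 matrix ([lowess_normalize()]).
#' @param design design table.
#' @param alpha significance level on the raw p value.
#' @param probes probe table override.
#' @return list with `counts` (data.frame `comparison`, `n_de`, `n_up`,
#'   `n_down`) and `results` (named list of [call_de()] tables).
#' @export
run_all_comparisons <- function(x, design, alpha = 0.01,
                                probes = attr(x, "probes")) {
  design <- validate_design(design)
  specs <- list()
  for (ti in TISSUES) {
    for (pair in asplit(combn(COHORTS, 2L), 2L)) {
      specs[[length(specs) + 1L]] <- list(a = pair[1], ta = ti, b = pair[2], tb = ti)
    }
  }
  for (co in COHORTS) {
    specs[[length(specs) + 1L]] <- list(a = co, ta = "fat_body", b = co, tb = "cuticle")
  }
  results <- list()
  counts <- lapply(specs, function(s) {
    have <- function(co, ti) any(design$cohort == co & design$tissue == ti)
    cmp <- comparison_spec(s$a, s$ta, s$b, s$tb, alpha = alpha)
    if (!have(s$a, s$ta) || !have(s$b, s$tb)) {
      warning(sprintf("comparison '%s' skipped: cohort/tissue missing from design",
                      cmp$label), call. = FALSE)
      return(data.frame(comparison = cmp$label, n_de = NA_integer_,
                        n_up = NA_integer_, n_down = NA_integer_))
    }
    de <- call_de(x, design, cmp, probes = probes)
    results[[cmp$label]] <<- de
    data.frame(comparison = cmp$label,
               n_de = sum(de$significant),
               n_up = sum(de$significant & de$log2_fc > 0),
               n_down = sum(de$significant & de$log2_fc < 0))
  })
  list(counts = do.call(rbind, counts), results = results)
}

#' Exclude miRNAs shared by the R+ and S+ differential sets
#'
#' Given the DE-vs-S- name sets of the infected resistant (R+) and infected
#' susceptible (S+) cohorts for one tissue and one direction, removes their
#' intersection from both and reports it separately.
#'
#' @param de_rplus,de_splus character vectors of miRNA names.
#' @return list with `rplus`, `splus` (filtered sets) and `shared`.
#' @examples
#' exclude_shared_duplicates(c("a", "b", "c"), c("b", "c", "d"))
#' @export
exclude_shared_duplicates <- function(de_rplus, de_splus) {
  shared <- intersect(de_rplus, de_splus)
  list(rplus = setdiff(de_rplus, shared),
       splus = setdiff(de_splus, shared),
       shared = shared)
}

#' Disjoint Venn partition of three miRNA sets
#'
#' Partitions the union of three named sets (each the DE-vs-S- set of one
#' cohort) into the 7 disjoint Venn cells: three singletons ("specifically"
#' regulated, present in exactly one set), three pairwise intersections and
#' the triple intersection.
#'
#' @param sets named list of three character vectors.
#' @return data.frame with columns `cell` (names joined by `&`), `size`,
#'   `members` (comma-joined, sorted).
#' @export
venn_partition <- function(sets) {
  stopifnot(is.list(sets), length(sets) == 3L, !is.null(names(sets)))
  nm <- names(sets)
  universe <- sort(unique(unlist(sets)))
  membership <- matrix(unlist(lapply(sets, function(s) universe %in% s)),
                       ncol = 3L)
  keys <- apply(membership, 1L, function(r) paste(nm[r], collapse = "&"))
  if (length(universe) == 0L) keys <- character(0)
  cells <- c(nm,
             paste(nm[c(1, 1, 2)], nm[c(2, 3, 3)], sep = "&"),
             paste(nm, collapse = "&"))
  out <- data.frame(cell = cells,
                    size = vapply(cells, function(k) sum(keys == k), 0L),
                    members = vapply(cells, function(k) {
                      paste(sort(universe[keys == k]), collapse = ",")
                    }, ""),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "universe") <- universe
  out
}

# direction-specific DE-vs-S- name sets for cohorts S+, R+, R- in one tissue
de_sets_vs_baseline <- function(x, design, tissue, direction = c("up", "down"),
                                alpha = 0.01, probes = attr(x, "probes")) {
  direction <- match.arg(direction)
  sets <- list()
  for (co in c("S+", "R+", "R-")) {
    de <- call_de(x, design, comparison_spec(co, tissue, "S-", alpha = alpha),
                  probes = probes)
    keep <- de$significant & (if (direction == "up") de$log2_fc > 0 else de$log2_fc < 0)
    sets[[co]] <- de$mirna[keep]
  }
  sets
}

#' Venn partition of the DE-vs-S- sets for one tissue
#'
#' Computes, per direction (up/down), the DE sets of S+, R+ and R- relative
#' to S-, applies the R+/S+ duplicate-exclusion rule (within the same
#' direction) before partitioning when `exclude_shared = TRUE`, and returns
#' the 7-cell partitions.
#'
#' @param x normalized log2 matrix.
#' @param design design table.
#' @param tissue `"cuticle"` or `"fat_body"`.
#' @param alpha significance level.
#' @param exclude_shared apply the R+/S+ duplicate exclusion first.
#' @param probes probe table override.
#' @return named list (`up`, `down`) of [venn_partition()] tables; the
#'   excluded R+/S+ intersection per direction is in `attr(, "shared")`.
#' @export
de_venn <- function(x, design, tissue, alpha = 0.01, exclude_shared = TRUE,
                    probes = attr(x, "probes")) {
  out <- list()
  shared <- list()
  for (dir in c("up", "down")) {
    sets <- de_sets_vs_baseline(x, design, tissue, dir, alpha, probes)
    if (exclude_shared) {
      ex <- exclude_shared_duplicates(sets[["R+"]], sets[["S+"]])
      sets[["R+"]] <- ex$rplus
      sets[["S+"]] <- ex$splus
      shared[[dir]] <- ex$shared
    }
    out[[dir]] <- venn_partition(sets)
  }
  attr(out, "shared") <- shared
  out
}

#' Truth-derived Venn partition from a planted-effect table
#'
#' Builds the same partition as [de_venn()] directly from the generator's
#' planted differential-expression table, for comparison with the recovered
#' partition.
#'
#' @param truth_de planted table (`mirna`, `cohort`, `tissue`, `log2_fc`).
#' @param tissue tissue to partition.
#' @param exclude_shared apply the R+/S+ duplicate exclusion.
#' @return named list (`up`, `down`) of [venn_partition()] tables.
#' @export
truth_venn <- function(truth_de, tissue, exclude_shared = TRUE) {
  out <- list()
  for (dir in c("up", "down")) {
    sets <- lapply(c("S+", "R+", "R-"), function(co) {
      sel <- truth_de$cohort == co & truth_de$tissue == tissue &
        (if (dir == "up") truth_de$log2_fc > 0 else truth_de$log2_fc < 0)
      unique(truth_de$mirna[sel])
    })
    names(sets) <- c("S+", "R+", "R-")
    if (exclude_shared) {
      ex <- exclude_shared_duplicates(sets[["R+"]], sets[["S+"]])
      sets[["R+"]] <- ex$rplus
      sets[["S+"]] <- ex$splus
    }
    out[[dir]] <- venn_partition(sets)
  }
  out
}

#' Membership agreement between two Venn partitions
#'
#' Over the union of miRNAs present in either partition, the fraction of
#' (miRNA, set) membership indicators on which the two partitions agree.
#'
#' @param a,b [venn_partition()] tables with identical cell structure.
#' @return agreement fraction in `[0, 1]` (1 when both are empty).
#' @export
venn_agreement <- function(a, b) {
  sets_of <- function(p) {
    singles <- p$cell[!grepl("&", p$cell, fixed = TRUE)]
    lapply(setNames(singles, singles), function(s) {
      idx <- vapply(strsplit(p$cell, "&", fixed = TRUE), function(k) s %in% k, TRUE)
      unlist(lapply(p$members[idx & p$size > 0], function(m) strsplit(m, ",")[[1]]))
    })
  }
  sa <- sets_of(a); sb <- sets_of(b)
  stopifnot(identical(names(sa), names(sb)))
  universe <- sort(unique(c(unlist(sa), unlist(sb))))
  if (length(universe) == 0L) return(1)
  agree <- vapply(names(sa), function(s) {
    sum((universe %in% sa[[s]]) == (universe %in% sb[[s]]))
  }, 0L)
  sum(agree) / (length(universe) * length(sa))
}
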