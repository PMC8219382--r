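# Statistical toolkit of the morphometric pipeline: exact Fisher tests on
# 2x2 count tables, rank tests for descriptor comparisons, domain-resolved
# mitotic frequency maps, and class A/B canalization curves.

#' Two-tailed Fisher exact test on a 2x2 table
#'
#' Exact two-sided p-value at fixed margins: the sum of hypergeometric
#' probabilities of all tables whose probability does not exceed that of
#' the observed table (with the customary `1 + 1e-7` slack for floating-
#' point ties).
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return two-sided p-value in (0, 1].
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2)) || any(tab < 0) ||
      any(abs(tab - round(tab)) > 1e-8))
    stop("need a 2x2 table of non-negative integers")
  tab <- round(tab)
  m <- sum(tab[1, ])                       # row-1 margin
  n <- sum(tab[2, ])
  k <- sum(tab[, 1])                       # column-1 margin
  if (m + n == 0 || k == 0 || k == m + n) return(1)
  x <- tab[1, 1]
  supp <- max(0, k - n):min(k, m)
  dens <- stats::dhyper(supp, m, n, k)
  min(1, sum(dens[dens <= dens[supp == x] * (1 + 1e-7)]))
}

#' Rank tests for paired / unpaired two-sample comparisons
#'
#' Wilcoxon signed-rank test (paired) or Mann-Whitney U test (unpaired),
#' both two-tailed: exact distributions for small samples without ties,
#' tie-corrected normal approximation otherwise (via [stats::wilcox.test]).
#' All-tied degenerate input returns `p = 1` with a flag.
#'
#' @param x,y numeric samples; equal lengths required when `paired`.
#' @param paired logical.
#' @param exact_max use the exact null distribution when both samples have
#'   at most this many observations (and no ties).
#' @return list with `statistic` (U for unpaired, V for paired),
#'   `p_value`, `method` and `degenerate`.
#' @export
rank_tests <- function(x, y, paired = FALSE, exact_max = 12) {
  if (paired && length(x) != length(y))
    stop("paired test needs equal-length samples")
  if (min(length(x), length(y)) < 3) stop("need n >= 3 per sample")
  if (paired && all(x == y)) {
    return(list(statistic = 0, p_value = 1,
                method = "wilcoxon_signed_rank", degenerate = TRUE))
  }
  if (!paired && length(unique(c(x, y))) == 1) {
    return(list(statistic = length(x) * length(y) / 2, p_value = 1,
                method = "mann_whitney_u", degenerate = TRUE))
  }
  has_ties <- anyDuplicated(if (paired) abs(x - y) else c(x, y)) > 0
  use_exact <- !has_ties && max(length(x), length(y)) <= exact_max
  wt <- suppressWarnings(stats::wilcox.test(x, y, paired = paired,
                                            exact = use_exact,
                                            correct = !use_exact))
  list(statistic = unname(wt$statistic),
       p_value = wt$p.value,
       method = if (paired) "wilcoxon_signed_rank" else "mann_whitney_u",
       exact = use_exact, degenerate = FALSE)
}

#' Domain-resolved mitotic frequency map
#'
#' For one stage: the frequency of mitoses per domain is the number of
#' reporter-positive cells in that domain over all included ovules,
#' divided by the total number of positive cells over all domains.
#' Ovules with no positive cell at all are excluded beforehand.
#'
#' @param scores data.frame with columns `ovule_id`, `stage`, then one
#'   integer count column per domain.
#' @param stage stage to tabulate (from [stage_levels()]), or `NULL` to
#'   use all rows.
#' @param domains character vector of domain column names (default: every
#'   column except `ovule_id`/`stage`).
#' @return list with `frequencies` (named, sums to 1), `total_events`,
#'   `n_ovules` (included), `n_excluded`.
#' @export
mitotic_frequency_map <- function(scores, stage = NULL, domains = NULL) {
  if (!is.null(stage)) scores <- scores[scores$stage == stage, , drop = FALSE]
  if (is.null(domains))
    domains <- setdiff(names(scores), c("ovule_id", "stage"))
  if (!nrow(scores)) stop("no ovules at the requested stage")
  cnt <- as.matrix(scores[, domains, drop = FALSE])
  if (any(cnt < 0)) stop("counts must be non-negative")
  keep <- rowSums(cnt) > 0
  cnt <- cnt[keep, , drop = FALSE]
  tot <- sum(cnt)
  if (tot == 0) stop("undefined frequency: zero mitotic events")
  list(frequencies = colSums(cnt) / tot, total_events = tot,
       n_ovules = sum(keep), n_excluded = sum(!keep))
}

#' Log2 fold-change map between two genotypes' frequency maps
#' @param map_mut,map_wt outputs of [mitotic_frequency_map()].
#' @return named numeric vector of log2 fold changes.
#' @export
mitotic_log2fc <- function(map_mut, map_wt) {
  log2(map_mut$frequencies / map_wt$frequencies)
}

#' Class A/B canalization analysis
#'
#' Per-stage percentage of class B ovules (two or more SMC candidates),
#' Fisher tests of each stage against the preceding stage and against the
#' first stage, and the resolution stage: the first stage whose class-B
#' frequency drops significantly versus the preceding stage.
#'
#' @param records data.frame with columns `stage`, `n_classA`, `n_classB`
#'   (one row per stage; a `genotype` column is allowed and ignored here).
#' @param alpha significance level for the Fisher contrasts.
#' @return list of class `classab_resolution`: per-stage table with `%B`
#'   and p-values, and `resolution_stage` (`NA` when no significant drop).
#' @export
classab_resolution <- function(records, alpha = 0.05) {
  stopifnot(all(c("stage", "n_classA", "n_classB") %in% names(records)))
  ord <- order(match(records$stage, stage_levels()))
  rec <- records[ord, , drop = FALSE]
  tot <- rec$n_classA + rec$n_classB
  if (sum(tot > 0) < 2) stop("need >= 2 stages with nonzero totals")
  pb <- 100 * rec$n_classB / tot
  ns <- nrow(rec)
  p_prev <- p_first <- rep(NA_real_, ns)
  for (i in 2:ns) {
    p_prev[i] <- fisher_exact_2x2(rbind(c(rec$n_classB[i - 1], rec$n_classA[i - 1]),
                                        c(rec$n_classB[i], rec$n_classA[i])))
    p_first[i] <- fisher_exact_2x2(rbind(c(rec$n_classB[1], rec$n_classA[1]),
                                         c(rec$n_classB[i], rec$n_classA[i])))
  }
  drop_sig <- which(p_prev < alpha & pb < c(NA, pb[-ns]))
  out <- list(table = data.frame(stage = rec$stage, n_classA = rec$n_classA,
                                 n_classB = rec$n_classB, perc_B = pb,
                                 p_vs_previous = p_prev, p_vs_first = p_first),
              resolution_stage = if (length(drop_sig)) rec$stage[min(drop_sig)]
                                 else NA_character_,
              alpha = alpha)
  class(out) <- "classab_resolution"
  out
}

#' @method print classab_resolution
#' @export
print.classab_resolution <- function(x, ...) {
  cat("<classab_resolution>\n")
  print(x$table, row.names = FALSE, digits = 3)
  cat("resolution stage:", x$resolution_stage, "(alpha =", x$alpha, ")\n")
  invisible(x)
}

#' Fisher contrast of class-B proportions between two genotypes at a stage
#' @param rec1,rec2 single-stage rows (lists/data.frames with `n_classA`,
#'   `n_classB`).
#' @return two-sided p-value.
#' @export
classab_genotype_test <- function(rec1, rec2) {
  fisher_exact_2x2(rbind(c(rec1$n_classB, rec1$n_classA),
                         c(rec2$n_classB, rec2$n_classA)))
}

# canonical cell-label vocabulary (OvuleViz-style exports)
CELL_LABELS <- c("SMC", "L1 apical", "L1 basal", "L1 dome", "L2,L3 apical",
                 "L2,L3 basal", "CC", "SMC contact", "other")

#' Load and validate an OvuleViz-style cell descriptor table
#'
#' Reads a CSV of per-cell descriptors (volume, area, sphericity, oblate
#' and prolate ellipticity) with genotype/stage/ovule/label annotations,
#' normalises the label vocabulary, and reports invalid rows (negative
#' descriptors, sphericity above 1, unknown labels).
#'
#' @param path CSV file (`;`-separated accepted via `sep`).
#' @param schema named character vector mapping canonical column names to
#'   file column names; defaults to identity for the canonical schema.
#' @param sep field separator.
#' @param strict error on unknown labels (TRUE) or keep them with a
#'   diagnostic (FALSE).
#' @return data.frame of valid rows; attributes `n_dropped` and
#'   `diagnostics` (character vector of row-level messages).
#' @export
load_cell_table <- function(path, schema = NULL, sep = ",", strict = FALSE) {
  canonical <- c("genotype", "stage", "ovule_id", "cell_id", "cell_label",
                 "volume", "area", "sphericity", "ellipticity_oblate",
                 "ellipticity_prolate")
  raw <- utils::read.csv(path, sep = sep, check.names = FALSE,
                         stringsAsFactors = FALSE)
  if (!is.null(schema)) {
    for (nm in names(schema)) {
      if (!schema[[nm]] %in% names(raw))
        stop("missing mapped column: ", schema[[nm]])
      names(raw)[names(raw) == schema[[nm]]] <- nm
    }
  }
  mandatory <- c("genotype", "stage", "ovule_id", "cell_label", "volume")
  miss <- setdiff(mandatory, names(raw))
  if (length(miss))
    stop("missing mandatory columns: ", paste(miss, collapse = ", "))
  for (nm in setdiff(canonical, names(raw))) raw[[nm]] <- NA
  raw <- raw[, canonical]
  if (!nrow(raw)) {
    attr(raw, "n_dropped") <- 0L
    attr(raw, "diagnostics") <- character(0)
    return(raw)
  }
  # vocabulary normalisation
  norm <- trimws(raw$cell_label)
  norm[tolower(norm) %in% c("smc", "spore mother cell")] <- "SMC"
  norm[tolower(norm) == "cc"] <- "CC"
  raw$cell_label <- norm
  diagnostics <- character(0)
  bad <- rep(FALSE, nrow(raw))
  num_bad <- (!is.na(raw$volume) & raw$volume < 0) |
    (!is.na(raw$area) & raw$area < 0) |
    (!is.na(raw$sphericity) & (raw$sphericity < 0 | raw$sphericity > 1))
  if (any(num_bad)) {
    diagnostics <- c(diagnostics,
                     sprintf("row %d: invalid descriptor value", which(num_bad)))
    bad <- bad | num_bad
  }
  unk <- !raw$cell_label %in% CELL_LABELS
  if (any(unk)) {
    msg <- sprintf("row %d: unknown label '%s'", which(unk),
                   raw$cell_label[unk])
    if (strict) stop(paste(msg, collapse = "; "))
    diagnostics <- c(diagnostics, msg)
  }
  out <- raw[!bad, , drop = FALSE]
  attr(out, "n_dropped") <- sum(bad)
  attr(out, "diagnostics") <- diagnostics
  out
}
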