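#' Sample metadata table
#'
#' Validates the per-sample metadata used for grouping and statistics. Sample
#' ids follow the "patientNumber-Region" convention (e.g. `89-Mot`).
#'
#' @param sample_id unique sample identifiers.
#' @param donor_id donor identifiers (one donor may supply several tissues).
#' @param tissue one of motor_cortex, occipital, spinal_cord, cerebellum,
#'   hippocampus, other.
#' @param condition `"ALS"` or `"control"`.
#' @param rin optional RNA integrity numbers (1-10).
#' @param age,sex optional.
#' @return data.frame of class `SampleMeta`.
#' @export
sample_meta <- function(sample_id, donor_id = sample_id,
                        tissue = "other", condition,
                        rin = NA_real_, age = NA_real_, sex = NA_character_) {
  stopifnot(!anyDuplicated(sample_id), !anyNA(condition))
  tissue <- rep_len(as.character(tissue), length(sample_id))
  ok_tissue <- c("motor_cortex", "occipital", "spinal_cord", "cerebellum",
                 "hippocampus", "other")
  if (!all(tissue %in% ok_tissue))
    stop("tissue must be one of: ", paste(ok_tissue, collapse = ", "))
  condition <- rep_len(as.character(condition), length(sample_id))
  if (!all(condition %in% c("ALS", "control")))
    stop("condition must be 'ALS' or 'control'")
  rin <- rep_len(as.numeric(rin), length(sample_id))
  if (any(!is.na(rin) & (rin < 1 | rin > 10)))
    stop("rin must lie in 1-10")
  out <- data.frame(sample_id = sample_id, donor_id = donor_id,
                    tissue = tissue, condition = condition, rin = rin,
                    age = rep_len(age, length(sample_id)),
                    sex = rep_len(sex, length(sample_id)),
                    stringsAsFactors = FALSE)
  class(out) <- c("SampleMeta", class(out))
  out
}

#' Relative cloning-frequency table
#'
#' Turns per-read assignments into a loci x samples table of counts and
#' relative cloning frequencies (percent of a sample's clones attributable to
#' each locus). Ambiguous calls appear as composite rows (`"a|b"`) and
#' unassigned reads as an explicit `unassigned` row, so every column's
#' frequencies sum to 100 (up to display rounding). Reads are included in
#' denominators regardless of status (configurable).
#'
#' @param assignments data.frame with at least `sample_id` and `loci`
#'   (composite locus label, `"unassigned"` for unassigned reads).
#' @param samples optional `SampleMeta`; its sample order is used and samples
#'   with zero reads are dropped with a warning.
#' @param include_unassigned keep the unassigned row in the denominator
#'   (default TRUE).
#' @return list of class `FrequencyTable`: `counts` and `frequency` matrices
#'   (rows = categories, columns = samples), `totals` per column.
#' @export
frequency_table <- function(assignments, samples = NULL,
                            include_unassigned = TRUE) {
  stopifnot(all(c("sample_id", "loci") %in% names(assignments)))
  if (!include_unassigned)
    assignments <- assignments[assignments$loci != "unassigned", ,
                               drop = FALSE]
  sample_ids <- if (!is.null(samples)) samples$sample_id
                else sort(unique(assignments$sample_id))
  empty <- setdiff(sample_ids, unique(assignments$sample_id))
  if (length(empty)) {
    warning("dropping sample(s) with 0 reads: ", paste(empty, collapse = ", "))
    sample_ids <- setdiff(sample_ids, empty)
  }
  assignments <- assignments[assignments$sample_id %in% sample_ids, ,
                             drop = FALSE]
  counts <- table(factor(assignments$loci),
                  factor(assignments$sample_id, levels = sample_ids))
  counts <- matrix(as.integer(counts), nrow = nrow(counts),
                   dimnames = dimnames(counts))
  frequency_table_from_counts(counts)
}

#' @param counts integer matrix (categories x samples).
#' @rdname frequency_table
#' @export
frequency_table_from_counts <- function(counts) {
  totals <- colSums(counts)
  freq <- sweep(counts, 2L, totals, "/") * 100
  structure(list(counts = counts, frequency = freq, totals = totals),
            class = "FrequencyTable")
}

#' Reconstruct counts from printed frequencies and column totals
#'
#' Inverse of the display rounding: `round(freq * total / 100)`. Used to turn
#' published percentage tables back into clone counts.
#'
#' @param frequency matrix of percentages (categories x samples).
#' @param totals per-column clone totals.
#' @return integer matrix of counts.
#' @export
counts_from_frequencies <- function(frequency, totals) {
  stopifnot(ncol(frequency) == length(totals))
  round(sweep(frequency, 2L, totals, "*") / 100)
}

#' @export
print.FrequencyTable <- function(x, digits = 2, ...) {
  cat("FrequencyTable:", nrow(x$counts), "categories x",
      ncol(x$counts), "samples (",
      sum(x$totals), "clones )\n")
  print(round(x$frequency, digits))
  invisible(x)
}

#' Aggregate a frequency table over sample groups
#'
#' Two first-class aggregation modes: `per_sample_mean` is the unweighted mean
#' of per-sample frequencies within a group (with min/max range), the mode
#' used when comparing disease and control groups; `pooled` is
#' `100 * sum(counts) / sum(totals)`, the share of all clones in the group.
#' The two coincide exactly when all samples in a group have equal totals.
#'
#' @param ft a `FrequencyTable`.
#' @param samples `SampleMeta` covering the table's columns.
#' @param group_by metadata column(s) to group samples by (e.g. `"condition"`
#'   or `c("condition", "tissue")`).
#' @param mode `"per_sample_mean"` or `"pooled"`.
#' @return data.frame: category, group key column(s), `n_samples`, `value`
#'   (percent) and, for per_sample_mean, `min`/`max`.
#' @export
aggregate_frequencies <- function(ft, samples,
                                  group_by = "condition",
                                  mode = c("per_sample_mean", "pooled")) {
  mode <- match.arg(mode)
  stopifnot(inherits(ft, "FrequencyTable"),
            all(group_by %in% names(samples)))
  cols <- colnames(ft$counts)
  meta <- samples[match(cols, samples$sample_id), , drop = FALSE]
  if (anyNA(meta$sample_id))
    stop("samples table does not cover all frequency-table columns")
  key <- interaction(meta[group_by], drop = TRUE, sep = "/")
  if (any(table(key) == 0L)) stop("empty group")
  groups <- split(seq_along(cols), key)
  out <- do.call(rbind, lapply(names(groups), function(g) {
    idx <- groups[[g]]
    if (mode == "per_sample_mean") {
      fr <- ft$frequency[, idx, drop = FALSE]
      data.frame(category = rownames(ft$counts), group = g,
                 n_samples = length(idx),
                 value = rowMeans(fr),
                 min = apply(fr, 1L, min), max = apply(fr, 1L, max),
                 stringsAsFactors = FALSE)
    } else {
      cnt <- ft$counts[, idx, drop = FALSE]
      data.frame(category = rownames(ft$counts), group = g,
                 n_samples = length(idx),
                 value = 100 * rowSums(cnt) / sum(ft$totals[idx]),
                 stringsAsFactors = FALSE)
    }
  }))
  attr(out, "mode") <- mode
  rownames(out) <- NULL
  out
}

#' Compare a per-sample metric between two groups
#'
#' Normality is screened per group with a Shapiro-Wilk test at `alpha`; if
#' both groups look normal a Welch two-sample t-test is used, otherwise a
#' rank-based test (two-sample rank-sum by default; the signed-rank variant is
#' available for paired designs).
#'
#' @param values numeric vector of per-sample measurements.
#' @param group two-level factor/character vector parallel to `values`.
#' @param alpha normality screening level (0.05).
#' @param paired use the Wilcoxon signed-rank test in the rank branch.
#' @param rank_test which rank-based fallback to use for unpaired designs.
#' @return list of class `GroupComparison`: `test` (`"welch_t"`,
#'   `"wilcoxon_rank_sum"` or `"wilcoxon_signed_rank"`), `statistic`,
#'   `p_value`, `shapiro_p` (per group), group summaries.
#' @export
compare_groups <- function(values, group, alpha = 0.05, paired = FALSE,
                           rank_test = c("rank_sum", "signed_rank")) {
  rank_test <- match.arg(rank_test)
  group <- as.character(group)
  lv <- unique(group)
  if (length(lv) != 2L) stop("exactly two groups required")
  x <- values[group == lv[1]]; y <- values[group == lv[2]]
  if (length(x) < 3L || length(y) < 3L) stop("insufficient samples (< 3 per group)")
  sw <- vapply(list(x, y), function(v) {
    if (length(unique(v)) < 3L) return(0)  # degenerate: not normal
    stats::shapiro.test(v)$p.value
  }, numeric(1))
  normal <- all(sw > alpha)
  if (normal && !paired) {
    ht <- stats::t.test(x, y, var.equal = FALSE)
    test <- "welch_t"
  } else if (normal && paired) {
    ht <- stats::t.test(x, y, paired = TRUE)
    test <- "paired_t"
  } else if (paired || rank_test == "signed_rank") {
    ht <- stats::wilcox.test(x, y, paired = TRUE, exact = FALSE)
    test <- "wilcoxon_signed_rank"
  } else {
    # exact null when sample sizes permit and there are no ties; the normal
    # approximation with continuity correction otherwise
    ht <- suppressWarnings(stats::wilcox.test(x, y))
    test <- "wilcoxon_rank_sum"
  }
  structure(list(test = test,
                 statistic = unname(ht$statistic),
                 p_value = ht$p.value,
                 shapiro_p = stats::setNames(sw, lv),
                 groups = stats::setNames(list(x, y), lv),
                 means = stats::setNames(c(mean(x), mean(y)), lv)),
            class = "GroupComparison")
}

#' @export
print.GroupComparison <- function(x, ...) {
  cat("Group comparison (", x$test, "): statistic = ",
      signif(x$statistic, 4), ", p = ", signif(x$p_value, 4), "\n", sep = "")
  cat("  group means:",
      paste(sprintf("%s = %.3g", names(x$means), x$means), collapse = ", "),
      "\n")
  invisible(x)
}

#' Ct table constructor / validator
#'
#' @param sample_id,target,ct parallel vectors of replicate Ct measurements;
#'   `target` names the assay (e.g. `HML2_gag`, `HERVW_env`, `GAPDH`).
#' @param reference_sample_id the high-expression reference sample whose fold
#'   change is defined as 1 (e.g. `"H9-hESC"`).
#' @param normalizer the normalisation target (default `"GAPDH"`).
#' @return data.frame of class `CtTable` with the reference and normalizer
#'   stored as attributes.
#' @export
ct_table <- function(sample_id, target, ct, reference_sample_id,
                     normalizer = "GAPDH") {
  stopifnot(length(sample_id) == length(target),
            length(target) == length(ct), all(ct > 0))
  out <- data.frame(sample_id = sample_id, target = target, ct = ct,
                    stringsAsFactors = FALSE)
  has_norm <- tapply(out$target, out$sample_id,
                     function(tg) any(tg == normalizer))
  if (!all(has_norm))
    warning("sample(s) without normalizer rows: ",
            paste(names(has_norm)[!has_norm], collapse = ", "))
  if (!reference_sample_id %in% out$sample_id)
    stop("reference sample '", reference_sample_id, "' absent from Ct table")
  attr(out, "reference_sample_id") <- reference_sample_id
  attr(out, "normalizer") <- normalizer
  class(out) <- c("CtTable", class(out))
  out
}

#' Delta-delta-Ct relative quantification
#'
#' For each sample, deltaCt = mean Ct(target) - mean Ct(normalizer); deltadeltaCt
#' subtracts the reference sample's deltaCt and the fold change is
#' 2^(-deltadeltaCt), so the reference sample's fold is 1 by construction. The
#' per-sample standard deviation of deltaCt is propagated from the replicate
#' Cts (sqrt of the summed replicate variances) and reported as a fold-change
#' range.
#'
#' @param ct a `CtTable`.
#' @param target which target to quantify (defaults to the first non-normalizer
#'   target in the table).
#' @return data.frame: `sample_id`, `n_replicates`, `delta_ct`, `sd_delta_ct`,
#'   `delta_delta_ct`, `fold_change`, `fold_lo`, `fold_hi`. Samples missing
#'   normalizer measurements are skipped with a warning.
#' @export
ddct_fold_change <- function(ct, target = NULL) {
  stopifnot(inherits(ct, "CtTable"))
  normalizer <- attr(ct, "normalizer")
  reference <- attr(ct, "reference_sample_id")
  if (is.null(target)) {
    targets <- setdiff(unique(ct$target), normalizer)
    if (!length(targets)) stop("no non-normalizer target in Ct table")
    target <- targets[1]
  }
  per_sample <- lapply(split(ct, ct$sample_id), function(d) {
    tg <- d$ct[d$target == target]
    nm <- d$ct[d$target == normalizer]
    if (!length(nm) || !length(tg)) return(NULL)
    sd_t <- if (length(tg) > 1L) stats::sd(tg) else 0
    sd_n <- if (length(nm) > 1L) stats::sd(nm) else 0
    data.frame(sample_id = d$sample_id[1],
               n_replicates = length(tg) + length(nm),
               delta_ct = mean(tg) - mean(nm),
               sd_delta_ct = sqrt(sd_t^2 + sd_n^2),
               stringsAsFactors = FALSE)
  })
  skipped <- names(per_sample)[vapply(per_sample, is.null, logical(1))]
  if (length(skipped))
    warning("skipping sample(s) without target+normalizer pairs: ",
            paste(skipped, collapse = ", "))
  res <- do.call(rbind, per_sample)
  if (!reference %in% res$sample_id)
    stop("reference sample lacks usable measurements")
  ref_dct <- res$delta_ct[res$sample_id == reference]
  res$delta_delta_ct <- res$delta_ct - ref_dct
  res$fold_change <- 2^(-res$delta_delta_ct)
  res$fold_lo <- 2^(-(res$delta_delta_ct + res$sd_delta_ct))
  res$fold_hi <- 2^(-(res$delta_delta_ct - res$sd_delta_ct))
  rownames(res) <- NULL
  res
}

#' Coefficient of determination of a least-squares line
#'
#' Simple QC regression, e.g. RNA integrity (RIN) against qPCR Ct values.
#'
#' @param x,y paired finite numeric vectors, n >= 3.
#' @return R-squared of `lm(y ~ x)`.
#' @export
qc_correlation <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 paired finite values")
  if (stats::var(x) == 0) stop("zero variance in x")
  summary(stats::lm(y ~ x))$r.squared
}
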