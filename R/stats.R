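#' Two-tailed paired t-test with effect size
#'
#' Paired comparison of eye-specific (or class-specific) measurements within
#' biological replicates. Cohen's d is computed on the within-replicate
#' differences (`mean(diff) / sd(diff)`); the confidence interval is the
#' 5/95% interval of the mean difference.
#'
#' @param arm1,arm2 numeric vectors of per-replicate values, aligned by
#'   replicate.
#' @param measurement_name label carried into the result.
#' @return one-row data.frame: `measurement_name`, `test`, `statistic`, `df`,
#'   `p`, `effect_size` (Cohen's d), `ci_low`, `ci_high`.
#' @export
paired_t <- function(arm1, arm2, measurement_name = "measurement") {
  stopifnot(length(arm1) == length(arm2), length(arm1) >= 2)
  diffs <- arm1 - arm2
  if (stats::sd(diffs) == 0) stop("degenerate pairs")
  tt <- stats::t.test(arm1, arm2, paired = TRUE, conf.level = 0.90)
  data.frame(measurement_name = measurement_name, test = "paired_t",
             statistic = unname(tt$statistic), df = unname(tt$parameter),
             p = tt$p.value,
             effect_size = mean(diffs) / stats::sd(diffs),
             ci_low = tt$conf.int[1], ci_high = tt$conf.int[2])
}

#' Two-sample Kolmogorov-Smirnov test with rank effect size
#'
#' Used for cumulative-distribution comparisons of pooled per-input
#' measurements. The p-value is the asymptotic two-sided KS p; epsilon
#' squared, the rank-based effect size (Kruskal-Wallis H divided by
#' `(n^2 - 1)/(n + 1)`), is attached for nonparametric reporting.
#'
#' @param x,y numeric samples (nonempty).
#' @param measurement_name label carried into the result.
#' @return one-row data.frame with the KS statistic `D`, `p`, and
#'   `effect_size` (epsilon squared).
#' @export
ks_two_sample <- function(x, y, measurement_name = "measurement") {
  stopifnot(length(x) >= 1, length(y) >= 1)
  ks <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
  data.frame(measurement_name = measurement_name, test = "ks",
             statistic = unname(ks$statistic), df = NA_real_,
             p = ks$p.value,
             effect_size = epsilon_squared(x, y),
             ci_low = NA_real_, ci_high = NA_real_)
}

#' Rank-based epsilon-squared effect size for two groups
#'
#' `H / ((n^2 - 1) / (n + 1))` where `H` is the Kruskal-Wallis statistic and
#' `n` the pooled sample size.
#'
#' @param x,y numeric samples.
#' @return epsilon squared in `[0, 1]`.
#' @export
epsilon_squared <- function(x, y) {
  g <- factor(rep(c("x", "y"), c(length(x), length(y))))
  h <- unname(stats::kruskal.test(c(x, y), g)$statistic)
  n <- length(x) + length(y)
  h / ((n^2 - 1) / (n + 1))
}

#' Benjamini-Hochberg FDR correction within condition families
#'
#' Step-up adjusted p-values, applied separately within each experimental
#' condition family; rejections at `p_adj <= alpha`.
#'
#' @param p p-values in `[0, 1]`.
#' @param alpha FDR level.
#' @param family optional family key per p-value; adjustment is performed
#'   within each family independently.
#' @return data.frame `p`, `family`, `p_adj`, `reject`, in input order.
#' @export
bh_fdr <- function(p, alpha = 0.05, family = NULL) {
  stopifnot(all(p >= 0 & p <= 1))
  if (length(p) == 0)
    return(data.frame(p = numeric(0), family = character(0),
                      p_adj = numeric(0), reject = logical(0)))
  if (is.null(family)) family <- rep("all", length(p))
  p_adj <- rep(NA_real_, length(p))
  for (f in unique(family)) {
    idx <- which(family == f)
    p_adj[idx] <- stats::p.adjust(p[idx], method = "BH")
  }
  data.frame(p = p, family = as.character(family), p_adj = p_adj,
             reject = p_adj <= alpha)
}

#' Replicate-level measurement table
#'
#' Reduces per-input tables from several biological replicates to one value
#' per (replicate, measurement, arm): eye-specific input densities, mAZ
#' fractions, median vesicle volumes, mean active-zone counts, mean volume
#' per active zone, clustered fractions and mean nearby-sAZ counts — the
#' measurement family the replicate-paired comparisons act on.
#'
#' @param replicates list, one element per replicate, each a list with
#'   `inputs` (from [classify_inputs()]), `neuropil_volume_um3`, and
#'   optionally `records` (from [label_clustered()]).
#' @param condition condition label for the family key.
#' @return long data.frame: `replicate_id`, `condition`, `measurement_name`,
#'   `arm`, `value`.
#' @export
replicate_summary <- function(replicates, condition = "cond") {
  rows <- list()
  add <- function(rid, name, arm, value) {
    if (is.na(value)) return()
    rows[[length(rows) + 1]] <<- data.frame(
      replicate_id = rid, condition = condition, measurement_name = name,
      arm = arm, value = value)
  }
  for (r in seq_along(replicates)) {
    rep_i <- replicates[[r]]
    inp <- rep_i$inputs
    if (is.null(inp) || nrow(inp) == 0) next
    gs <- summarize_by_group(inp, rep_i$neuropil_volume_um3)
    for (i in seq_len(nrow(gs))) {
      arm <- paste(gs$eye[i], gs$input_class[i], sep = ".")
      add(r, "density", arm, gs$density_per_um3[i])
      add(r, "median_vesicle_volume", arm, gs$median_vesicle_volume_um3[i])
      add(r, "mean_az_count", arm, gs$mean_az_count[i])
      add(r, "volume_per_az", arm, gs$mean_volume_per_az[i])
    }
    for (e in unique(gs$eye))
      add(r, "maz_fraction", e, gs$maz_fraction[match(e, gs$eye)])
    if (!is.null(rep_i$records)) {
      rec <- rep_i$records
      for (e in unique(rec$eye)) for (cl in unique(rec$input_class)) {
        s <- rec[rec$eye %in% e & rec$input_class == cl, , drop = FALSE]
        if (!nrow(s)) next
        arm <- paste(e, cl, sep = ".")
        add(r, "clustered_fraction", arm, mean(s$clustered))
        if (any(s$clustered))
          add(r, "mean_nearby_saz", arm, mean(s$n_nearby_saz[s$clustered]))
      }
    }
  }
  if (!length(rows))
    return(data.frame(replicate_id = integer(0), condition = character(0),
                      measurement_name = character(0), arm = character(0),
                      value = numeric(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Paired eye comparisons across a replicate table
#'
#' For every measurement with both a dominant and a non_dominant arm present
#' in all replicates, runs the paired t-test and attaches BH-adjusted
#' p-values within the condition family.
#'
#' @param summary_table output of [replicate_summary()].
#' @param alpha FDR level.
#' @return data.frame of test results with `p_adj` and `reject`.
#' @export
eye_paired_tests <- function(summary_table, alpha = 0.05) {
  out <- list()
  for (cond in unique(summary_table$condition)) {
    st <- summary_table[summary_table$condition == cond, , drop = FALSE]
    st$cls <- sub("^[^.]*\\.?", "", st$arm)
    st$eye <- sub("\\..*$", "", st$arm)
    for (meas in unique(st$measurement_name)) {
      for (cl in unique(st$cls[st$measurement_name == meas])) {
        s <- st[st$measurement_name == meas & st$cls == cl, , drop = FALSE]
        a1 <- s[s$eye == "dominant", ]
        a2 <- s[s$eye == "non_dominant", ]
        common <- intersect(a1$replicate_id, a2$replicate_id)
        if (length(common) < 2) next
        v1 <- a1$value[match(common, a1$replicate_id)]
        v2 <- a2$value[match(common, a2$replicate_id)]
        res <- tryCatch(paired_t(v1, v2, paste(meas, cl, sep = ".")),
                        error = function(e) NULL)
        if (is.null(res)) next
        res$condition <- cond
        out[[length(out) + 1]] <- res
      }
    }
  }
  if (!length(out))
    return(data.frame(measurement_name = character(0), test = character(0),
                      statistic = numeric(0), df = numeric(0), p = numeric(0),
                      effect_size = numeric(0), ci_low = numeric(0),
                      ci_high = numeric(0), condition = character(0),
                      p_adj = numeric(0), reject = logical(0)))
  res <- do.call(rbind, out)
  adj <- bh_fdr(res$p, alpha, res$condition)
  res$p_adj <- adj$p_adj
  res$reject <- adj$reject
  rownames(res) <- NULL
  res
}
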