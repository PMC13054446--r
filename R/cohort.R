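# Censoring-aware aggregation of single-cell records and rank-based
# longitudinal comparisons.

.AGE_GROUPS <- list("6-12" = c(6, 12), "23-35" = c(23, 35),
                    "54-87" = c(54, 87))

.age_group <- function(age_weeks) {
  out <- rep(NA_character_, length(age_weeks))
  for (g in names(.AGE_GROUPS)) {
    rng <- .AGE_GROUPS[[g]]
    out[!is.na(age_weeks) & age_weeks >= rng[1] & age_weeks <= rng[2]] <- g
  }
  factor(out, levels = names(.AGE_GROUPS))
}

#' Summarize a cohort of single-cell records
#'
#' Aggregates the master single-cell table per organ and age (weeks):
#' IgG-secreting cell counts, antigen-specific counts and percentage, mean
#' K_D (nM) and mean secretion rate among specific cells, and the
#' LOW/MEDIUM/HIGH affinity-class proportions. Censored rates contribute at
#' their censored (boundary) value; extrapolated K_D values below 10 pM are
#' floored at 10 pM for summaries (plotting-parity rule). Mean affinity is
#' the arithmetic mean on the nM scale by default; set `geometric = TRUE`
#' for the geometric mean. Empty strata are absent from the output, not
#' zero rows.
#'
#' @param records master table from [infer_cells()] (or any data.frame with
#'   columns kd, kd_flag, secretion_rate, is_gpi_specific, affinity_class,
#'   organ, age_weeks).
#' @param geometric use geometric instead of arithmetic mean K_D.
#' @return an object of class `cohort_summary`: list with `by_stratum`
#'   (per organ x age data.frame), `overall` (one-row data.frame),
#'   `censor_tally` (rate/kd flag counts), and `age_group_kd` (pooled
#'   specific K_D values, nM, per age group).
#' @export
summarize_cohort <- function(records, geometric = FALSE) {
  req <- c("kd", "kd_flag", "secretion_rate", "is_gpi_specific",
           "affinity_class", "organ", "age_weeks")
  stopifnot(all(req %in% names(records)))
  r <- records
  r$kd_nM <- pmax(r$kd, .KD_PLOT_FLOOR) * 1e9

  one <- function(g) {
    sp <- g[g$is_gpi_specific %in% TRUE, , drop = FALSE]
    mean_fun <- if (geometric) function(x) exp(mean(log(x))) else mean
    data.frame(
      n_igg_sc = nrow(g),
      n_gpi_specific = nrow(sp),
      percent_specific = 100 * nrow(sp) / max(nrow(g), 1),
      mean_kd_nM = if (nrow(sp)) mean_fun(sp$kd_nM) else NA_real_,
      mean_secretion_rate = if (nrow(g)) mean(g$secretion_rate, na.rm = TRUE)
        else NA_real_,
      prop_low = if (nrow(sp)) mean(sp$affinity_class == "LOW") else NA_real_,
      prop_medium = if (nrow(sp)) mean(sp$affinity_class == "MEDIUM")
        else NA_real_,
      prop_high = if (nrow(sp)) mean(sp$affinity_class == "HIGH")
        else NA_real_)
  }

  key <- interaction(r$organ, r$age_weeks, drop = TRUE)
  by_stratum <- NULL
  if (nrow(r) > 0) {
    pieces <- lapply(split(r, key), one)
    meta <- do.call(rbind, lapply(split(r, key), function(g) {
      data.frame(organ = g$organ[1], age_weeks = g$age_weeks[1])
    }))
    by_stratum <- cbind(meta, do.call(rbind, pieces))
    rownames(by_stratum) <- NULL
    by_stratum <- by_stratum[order(by_stratum$organ, by_stratum$age_weeks), ]
  }

  grp <- .age_group(r$age_weeks)
  sp_all <- r[r$is_gpi_specific %in% TRUE, , drop = FALSE]
  age_group_kd <- split(sp_all$kd_nM, .age_group(sp_all$age_weeks))

  structure(list(
    by_stratum = by_stratum,
    overall = one(r),
    censor_tally = list(rate = table(r$rate_flag), kd = table(r$kd_flag)),
    age_group_kd = age_group_kd
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  o <- x$overall
  cat("Cohort summary:", o$n_igg_sc, "IgG-SC,", o$n_gpi_specific,
      "antigen-specific (", round(o$percent_specific, 1), "% )\n")
  if (o$n_gpi_specific > 0) {
    cat("  specific cells: mean K_D", round(o$mean_kd_nM, 1),
        "nM; class proportions LOW/MED/HIGH",
        paste(round(100 * c(o$prop_low, o$prop_medium, o$prop_high), 1),
              collapse = "/"), "%\n")
  }
  cat("  mean secretion rate", round(o$mean_secretion_rate, 1),
      "molecules/s\n")
  if (!is.null(x$by_stratum)) {
    cat("  strata:", nrow(x$by_stratum), "(organ x age)\n")
  }
  invisible(x)
}

#' Rank-based comparisons between consecutive timepoints
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) tests between each pair of
#' consecutive timepoints; strata with fewer than 3 values are skipped with
#' a notice. Significance convention: p <= 0.05.
#'
#' @param values numeric vector of single-cell values.
#' @param timepoint parallel vector of timepoints (sortable).
#' @return data.frame with one row per consecutive pair: `from`, `to`,
#'   `n_from`, `n_to`, `statistic`, `p_value`, `skipped`.
#' @export
compare_timepoints <- function(values, timepoint) {
  stopifnot(length(values) == length(timepoint))
  keep <- is.finite(values) & !is.na(timepoint)
  values <- values[keep]; timepoint <- timepoint[keep]
  tps <- sort(unique(timepoint))
  if (length(tps) < 2) {
    return(data.frame(from = numeric(0), to = numeric(0),
                      n_from = integer(0), n_to = integer(0),
                      statistic = numeric(0), p_value = numeric(0),
                      skipped = logical(0)))
  }
  out <- lapply(seq_len(length(tps) - 1), function(i) {
    a <- values[timepoint == tps[i]]
    b <- values[timepoint == tps[i + 1]]
    if (length(a) < 3 || length(b) < 3) {
      message("skipping ", tps[i], " vs ", tps[i + 1],
              ": stratum with n < 3")
      return(data.frame(from = tps[i], to = tps[i + 1],
                        n_from = length(a), n_to = length(b),
                        statistic = NA_real_, p_value = NA_real_,
                        skipped = TRUE))
    }
    w <- wilcox.test(a, b, alternative = "two.sided", exact = FALSE)
    data.frame(from = tps[i], to = tps[i + 1],
               n_from = length(a), n_to = length(b),
               statistic = unname(w$statistic), p_value = w$p.value,
               skipped = FALSE)
  })
  do.call(rbind, out)
}

#' Dunn's post-hoc test for pairwise group comparisons after Kruskal-Wallis
#'
#' Pairwise z statistics on mean ranks with the standard tie correction,
#' \deqn{z_{ij} = \frac{\bar R_i - \bar R_j}{\sqrt{\left(\frac{N(N+1)}{12}
#'   - \frac{\sum_t (t^3 - t)}{12 (N-1)}\right)
#'   \left(\frac{1}{n_i} + \frac{1}{n_j}\right)}},}
#' with p values adjusted for multiple comparisons.
#'
#' @param values numeric vector.
#' @param group grouping factor.
#' @param p_adjust adjustment method passed to [stats::p.adjust()].
#' @return data.frame with one row per group pair: `group1`, `group2`, `z`,
#'   `p_value`, `p_adjusted`.
#' @export
dunn_test <- function(values, group, p_adjust = "bonferroni") {
  keep <- is.finite(values) & !is.na(group)
  values <- values[keep]; group <- factor(group[keep])
  g <- levels(group)
  if (length(g) < 2) stop("need >= 2 groups")
  N <- length(values)
  rk <- rank(values)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  rbar <- tapply(rk, group, mean)
  n <- tapply(rk, group, length)
  pairs <- utils::combn(g, 2)
  z <- apply(pairs, 2, function(p) {
    (rbar[p[1]] - rbar[p[2]]) /
      sqrt((N * (N + 1) / 12 - tie_corr) * (1 / n[p[1]] + 1 / n[p[2]]))
  })
  p <- 2 * pnorm(-abs(z))
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ], z = unname(z),
             p_value = unname(p),
             p_adjusted = p.adjust(unname(p), method = p_adjust))
}

#' Compare pooled affinity distributions across age groups
#'
#' Kruskal-Wallis test across the three age groups (6-12, 23-35, 54-87
#' weeks) of pooled antigen-specific K_D values, followed by Dunn's
#' pairwise test; groups with fewer than 3 values are dropped with a
#' notice.
#'
#' @param summary a [summarize_cohort()] result.
#' @param p_adjust adjustment for Dunn's pairwise p values.
#' @return list with `kruskal` (htest or NULL) and `dunn` (data.frame or
#'   NULL).
#' @export
compare_age_groups <- function(summary, p_adjust = "bonferroni") {
  stopifnot(inherits(summary, "cohort_summary"))
  kd <- summary$age_group_kd
  kd <- kd[vapply(kd, length, integer(1)) >= 3]
  if (length(kd) < 2) {
    message("fewer than 2 age groups with n >= 3: tests skipped")
    return(list(kruskal = NULL, dunn = NULL))
  }
  values <- unlist(kd, use.names = FALSE)
  group <- rep(names(kd), lengths(kd))
  list(kruskal = kruskal.test(values, factor(group)),
       dunn = dunn_test(values, group, p_adjust = p_adjust))
}
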