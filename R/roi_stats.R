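#' Proportional face and upper-face fixation time per condition cell
#'
#' Intersects labelled fixations with the coded speaking/listening periods
#' (fixations straddling a period boundary contribute only their within-period
#' portion) and computes, per participant x task x speech state:
#'
#' * `face_prop` — face fixation time proportional to valid total fixation
#'   time within the periods (fixations labelled `"unclassifiable"` count as
#'   data loss and are excluded from the denominator);
#' * `upper_prop` — upper-face fixation time proportional to face fixation
#'   time, defined only when face fixation time is positive;
#' * `valid_time` and `loss_frac` — when the raw gaze table is supplied,
#'   valid time is the sampled time with a valid gaze flag inside the periods
#'   and `loss_frac = 1 - valid_time / period_time`.
#'
#' Cells with zero classified fixation time are flagged `missing` and are
#' excluded listwise by [mixed_anova_2x2x2()].
#'
#' @param labeled_fixations fixation table with columns `participant`, `task`,
#'   `t_start`, `t_end`, `duration`, `label`.
#' @param periods coded periods from [code_speech_table()].
#' @param gaze optional raw gaze table for loss accounting.
#' @param config an [analysis_config()].
#' @return a tibble with one row per participant x task x speech state.
#' @export
compute_proportions <- function(labeled_fixations, periods, gaze = NULL,
                                config = analysis_config()) {
  dt <- 1000 / config$sampling_rate_hz
  cells <- dplyr::distinct(periods, .data$participant, .data$task, .data$role)
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    p <- cells$participant[i]; tk <- cells$task[i]; role <- cells$role[i]
    per <- periods[periods$participant == p & periods$task == tk &
                     periods$role == role, , drop = FALSE]
    fx <- labeled_fixations[labeled_fixations$participant == p &
                              labeled_fixations$task == tk, , drop = FALSE]
    dur_by_label <- c(upper = 0, lower = 0, outside = 0, unclassifiable = 0)
    if (nrow(fx)) {
      clipped <- clip_to_intervals(fx$t_start, fx$t_end, per$t_start, per$t_end)
      agg <- tapply(clipped, fx$label, sum)
      dur_by_label[names(agg)] <- agg
    }
    classified <- dur_by_label[["upper"]] + dur_by_label[["lower"]] +
      dur_by_label[["outside"]]
    face <- dur_by_label[["upper"]] + dur_by_label[["lower"]]
    period_time <- sum(per$t_end - per$t_start)
    valid_time <- NA_real_
    if (!is.null(gaze)) {
      g <- gaze[gaze$participant == p & gaze$task == tk, , drop = FALSE]
      in_per <- rep(FALSE, nrow(g))
      for (j in seq_len(nrow(per))) {
        in_per <- in_per | (g$t >= per$t_start[j] & g$t < per$t_end[j])
      }
      valid_time <- sum(in_per & g$valid) * dt
    }
    out[[i]] <- tibble::tibble(
      participant = p, task = tk, speech_state = role,
      face_prop = if (classified > 0) face / classified else NA_real_,
      upper_prop = if (face > 0) dur_by_label[["upper"]] / face else NA_real_,
      fix_time = classified,
      period_time = period_time,
      valid_time = valid_time,
      loss_frac = if (!is.na(valid_time) && period_time > 0)
        1 - valid_time / period_time else NA_real_,
      missing = classified <= 0
    )
  }
  dplyr::bind_rows(out)
}

# total overlap of each [a, b] interval with a set of (clip) intervals
clip_to_intervals <- function(a, b, starts, ends) {
  tot <- numeric(length(a))
  for (j in seq_along(starts)) {
    tot <- tot + pmax(0, pmin(b, ends[j]) - pmax(a, starts[j]))
  }
  tot
}

#' 2 x 2 x 2 mixed ANOVA on proportional looking time
#'
#' Fits the study's mixed design — one between-subject factor (Group) and two
#' within-subject factors (Speech: speaking/listening; Task: introduction/
#' storytelling) — on a chosen proportional looking measure, with type-III
#' sums of squares in the repeated-measures formulation (via [car::Anova()]).
#' Participants with any missing cell are removed listwise, since the
#' classical mixed ANOVA requires complete within-subject data. With two
#' levels per within factor sphericity holds trivially and no correction is
#' applied. Partial eta squared is `SS_effect / (SS_effect + SS_error)` with
#' the error term of the effect's own stratum.
#'
#' @param outcomes output of [compute_proportions()] joined with a `group`
#'   column.
#' @param dependent `"face_prop"` or `"upper_prop"`.
#' @return a tibble with one row per effect (Group, Speech, Task and their
#'   interactions): `effect`, `df1`, `df2`, `F`, `p`, `partial_eta_sq`, plus
#'   attribute `n_included` (participants after listwise deletion).
#' @export
mixed_anova_2x2x2 <- function(outcomes, dependent = c("face_prop", "upper_prop")) {
  dependent <- match.arg(dependent)
  stopifnot(all(c("participant", "group", "task", "speech_state") %in% names(outcomes)))
  d <- outcomes
  d$y <- d[[dependent]]
  if ("missing" %in% names(d)) d$y[d$missing] <- NA
  wide <- tidyr::pivot_wider(
    d[, c("participant", "group", "task", "speech_state", "y")],
    names_from = c("speech_state", "task"), values_from = "y",
    names_sep = "."
  )
  cell_cols <- setdiff(names(wide), c("participant", "group"))
  if (length(cell_cols) != 4) {
    stop_dyad("insufficient-data",
              "expected 4 speech_state x task cells, found ", length(cell_cols))
  }
  cell_cols <- sort(cell_cols)
  wide <- wide[complete.cases(wide[, cell_cols]), , drop = FALSE]
  wide$group <- factor(wide$group)
  if (nlevels(wide$group) != 2 || any(table(wide$group) < 2)) {
    stop_dyad("insufficient-data",
              "mixed ANOVA needs two groups with at least 2 complete participants each")
  }
  Y <- as.matrix(wide[, cell_cols])
  idata <- do.call(rbind, strsplit(cell_cols, ".", fixed = TRUE))
  idata <- data.frame(Speech = factor(idata[, 1]), Task = factor(idata[, 2]))
  # sum-to-zero contrasts so the type-III within-effects average over groups
  mlm <- stats::lm(Y ~ group, data = wide,
                   contrasts = list(group = "contr.sum"))
  an <- car::Anova(mlm, idata = idata, idesign = ~ Speech * Task, type = 3)
  uni <- summary(an, multivariate = FALSE)$univariate.tests
  tab <- as.data.frame(unclass(uni))
  tab$effect <- rownames(uni)
  tab <- tab[tab$effect != "(Intercept)", , drop = FALSE]
  effect_name <- function(x) {
    x <- gsub("group", "Group", x)
    parts <- strsplit(x, ":", fixed = TRUE)[[1]]
    # present between factor last in interactions, matching the Speech x Group style
    paste(c(setdiff(parts, "Group"), intersect(parts, "Group")), collapse = ":")
  }
  res <- tibble::tibble(
    effect = vapply(tab$effect, effect_name, character(1)),
    df1 = tab[["num Df"]],
    df2 = tab[["den Df"]],
    F = tab[["F value"]],
    p = tab[["Pr(>F)"]],
    partial_eta_sq = tab[["Sum Sq"]] / (tab[["Sum Sq"]] + tab[["Error SS"]])
  )
  attr(res, "n_included") <- nrow(wide)
  res
}

# ---- exact nonparametric follow-up tests ------------------------------------

#' Wilcoxon signed-rank test with exact tie-safe p-values
#'
#' Two-sided paired signed-rank test. Zero differences are dropped; absolute
#' differences are midranked. For 25 or fewer informative pairs the null
#' distribution of the positive-rank sum is computed exactly by dynamic
#' programming over the (possibly tied) ranks; otherwise the normal
#' approximation with tie correction is used. The effect size is
#' \eqn{r = Z / \sqrt{N}} with N the number of pairs entered.
#'
#' @param x,y paired samples.
#' @return a tibble: `V` (positive-rank sum), `z`, `p`, `r`, `n`, `method`.
#' @examples
#' wilcoxon_signed_rank(c(2, 4, 6), c(1, 2, 3))  # exact p = 0.25
#' @export
wilcoxon_signed_rank <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- !is.na(x) & !is.na(y)
  d <- x[keep] - y[keep]
  n_pairs <- length(d)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop_dyad("degenerate-data", "all paired differences are zero")
  rk <- rank(abs(d))
  V <- sum(rk[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(rk)
  sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- if (sig2 > 0) (V - mu) / sqrt(sig2) else 0
  if (n <= 25) {
    # exact distribution of 2V over all 2^n sign assignments (doubled midranks
    # are integers, so a subset-sum DP applies even with ties)
    r2 <- as.integer(round(2 * rk))
    tot <- sum(r2)
    f <- numeric(tot + 1)
    f[1] <- 1
    for (r in r2) {
      f[(r + 1):(tot + 1)] <- f[(r + 1):(tot + 1)] + f[1:(tot + 1 - r)]
    }
    v2 <- as.integer(round(2 * V))
    cdf_le <- sum(f[1:(v2 + 1)]) / 2^n
    cdf_ge <- sum(f[(v2 + 1):(tot + 1)]) / 2^n
    p <- min(1, 2 * min(cdf_le, cdf_ge))
    method <- "exact"
  } else {
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal"
  }
  tibble::tibble(V = V, z = z, p = p, r = z / sqrt(n_pairs), n = n_pairs,
                 method = method)
}

#' Mann-Whitney U test with exact tie-safe p-values
#'
#' Two-sided two-sample rank test. For group sizes of at most 10 each, the
#' null distribution of U is computed exactly by enumerating every split of
#' the combined midranks; otherwise the normal approximation with tie
#' correction is used. The effect size is \eqn{r = Z / \sqrt{n_1 + n_2}}.
#'
#' @param x,y independent samples.
#' @return a tibble: `U` (for the first sample), `z`, `p`, `r`, `n1`, `n2`,
#'   `method`.
#' @examples
#' mann_whitney_u(1:3, 4:6)  # U = 0, exact p = 0.1
#' @export
mann_whitney_u <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  if (n1 < 1 || n2 < 1) stop_dyad("insufficient-data", "both samples must be non-empty")
  rk <- rank(c(x, y))
  R1 <- sum(rk[seq_len(n1)])
  U <- R1 - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(rk)
  sig2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  z <- if (sig2 > 0) (U - mu) / sqrt(sig2) else 0
  if (n1 <= 10 && n2 <= 10) {
    splits <- utils::combn(n, n1)
    u_all <- colSums(matrix(rk[splits], nrow = n1)) - n1 * (n1 + 1) / 2
    eps <- 1e-9
    p <- min(1, 2 * min(mean(u_all <= U + eps), mean(u_all >= U - eps)))
    method <- "exact"
  } else {
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal"
  }
  tibble::tibble(U = U, z = z, p = p, r = z / sqrt(n), n1 = n1, n2 = n2,
                 method = method)
}

#' Spearman rank correlation
#'
#' Rho is the Pearson correlation of the midranks (tie-safe). The two-sided
#' p-value is exact (via [stats::cor.test()]) for untied samples of modest
#' size, and uses the t approximation `t = rho * sqrt((n-2)/(1-rho^2))`
#' otherwise.
#'
#' @param x,y paired observations (at least 4 complete pairs).
#' @return a tibble: `rho`, `p`, `n`.
#' @export
spearman_cor <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 4) stop_dyad("insufficient-data", "need at least 4 complete pairs")
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    stop_dyad("undefined-correlation", "a constant vector has no rank correlation")
  }
  rho <- cor(rank(x), rank(y))
  has_ties <- anyDuplicated(x) || anyDuplicated(y)
  if (!has_ties && n <= 50) {
    p <- suppressWarnings(
      stats::cor.test(x, y, method = "spearman", exact = TRUE)$p.value)
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * pt(-abs(tstat), n - 2)
  }
  tibble::tibble(rho = rho, p = p, n = n)
}

#' Nonparametric follow-up contrasts for the mixed design
#'
#' Collapses the condition cells as required and applies the matching
#' nonparametric test: Wilcoxon signed-rank for within-subject contrasts
#' (speech, task), Mann-Whitney U for between-group contrasts (overall, or
#' within one speech state). A Shapiro-Wilk normality screen per condition
#' cell is available via [shapiro_screen()].
#'
#' @param outcomes output of [compute_proportions()] with a `group` column.
#' @param dependent `"face_prop"` or `"upper_prop"`.
#' @param contrast one of `"speech"`, `"task"`, `"group"`,
#'   `"group_speaking"`, `"group_listening"`.
#' @return a one-row tibble from [wilcoxon_signed_rank()] or
#'   [mann_whitney_u()], with the contrast name prepended.
#' @export
followup_tests <- function(outcomes, dependent = c("face_prop", "upper_prop"),
                           contrast = c("speech", "task", "group",
                                        "group_speaking", "group_listening")) {
  dependent <- match.arg(dependent)
  contrast <- match.arg(contrast)
  d <- outcomes
  d$y <- d[[dependent]]
  if ("missing" %in% names(d)) d$y[d$missing] <- NA
  per_part <- function(filter_state = NULL) {
    dd <- d
    if (!is.null(filter_state)) dd <- dd[dd$speech_state == filter_state, ]
    agg <- stats::aggregate(y ~ participant + group, data = dd, FUN = mean,
                            na.action = stats::na.omit)
    agg
  }
  res <- switch(contrast,
    speech = {
      a <- stats::aggregate(y ~ participant + speech_state, data = d, FUN = mean)
      w <- tidyr::pivot_wider(a, names_from = "speech_state", values_from = "y")
      wilcoxon_signed_rank(w$listening, w$speaking)
    },
    task = {
      a <- stats::aggregate(y ~ participant + task, data = d, FUN = mean)
      w <- tidyr::pivot_wider(a, names_from = "task", values_from = "y")
      cols <- setdiff(names(w), "participant")
      wilcoxon_signed_rank(w[[cols[1]]], w[[cols[2]]])
    },
    group = {
      a <- per_part()
      g <- sort(unique(a$group))
      mann_whitney_u(a$y[a$group == g[1]], a$y[a$group == g[2]])
    },
    group_speaking = {
      a <- per_part("speaking")
      g <- sort(unique(a$group))
      mann_whitney_u(a$y[a$group == g[1]], a$y[a$group == g[2]])
    },
    group_listening = {
      a <- per_part("listening")
      g <- sort(unique(a$group))
      mann_whitney_u(a$y[a$group == g[1]], a$y[a$group == g[2]])
    }
  )
  tibble::tibble(contrast = contrast, dependent = dependent, res)
}

#' @rdname followup_tests
#' @export
shapiro_screen <- function(outcomes, dependent = c("face_prop", "upper_prop")) {
  dependent <- match.arg(dependent)
  d <- outcomes
  d$y <- d[[dependent]]
  cells <- dplyr::distinct(d, .data$group, .data$task, .data$speech_state)
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    y <- d$y[d$group == cells$group[i] & d$task == cells$task[i] &
               d$speech_state == cells$speech_state[i]]
    y <- y[!is.na(y)]
    sw <- if (length(y) >= 3 && length(unique(y)) > 1)
      stats::shapiro.test(y) else list(statistic = NA_real_, p.value = NA_real_)
    out[[i]] <- tibble::tibble(cells[i, ], W = unname(sw$statistic),
                               p = sw$p.value, n = length(y))
  }
  dplyr::bind_rows(out)
}

#' Trait analysis: group comparisons and trait-gaze correlations
#'
#' Compares AQ and LSAS totals between groups with a pooled two-sample t-test
#' (classical df n1 + n2 - 2; Welch available via `config$pooled_t = FALSE`)
#' and Cohen's d, and computes Spearman correlations between each trait and
#' the gaze metrics, separately per group and speech state: proportional face
#' looking per task, and proportional upper-face looking collapsed across
#' tasks.
#'
#' @param outcomes output of [compute_proportions()] with a `group` column.
#' @param traits trait table: `participant`, `group`, `aq`, `lsas`.
#' @param config an [analysis_config()].
#' @return a list with `group_tests` (trait, per-group means/SDs, t, df, p,
#'   cohens_d) and `correlations` (group, speech_state, metric, trait, rho,
#'   p, n).
#' @export
trait_analysis <- function(outcomes, traits, config = analysis_config()) {
  g <- sort(unique(traits$group))
  if (length(g) != 2) stop_dyad("insufficient-data", "trait analysis needs two groups")
  group_tests <- dplyr::bind_rows(lapply(c("aq", "lsas"), function(tr) {
    x <- traits[[tr]][traits$group == g[1]]
    y <- traits[[tr]][traits$group == g[2]]
    tt <- stats::t.test(x, y, var.equal = isTRUE(config$pooled_t))
    sp <- sqrt(((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
                 (length(x) + length(y) - 2))
    tibble::tibble(trait = toupper(tr), group_1 = g[1], group_2 = g[2],
                   mean_1 = mean(x), sd_1 = sd(x), mean_2 = mean(y), sd_2 = sd(y),
                   t = unname(tt$statistic), df = unname(tt$parameter),
                   p = tt$p.value, cohens_d = abs(mean(x) - mean(y)) / sp)
  }))

  d <- outcomes
  if ("missing" %in% names(d)) {
    d$face_prop[d$missing] <- NA
    d$upper_prop[d$missing] <- NA
  }
  tasks <- sort(unique(d$task))
  metric_table <- function(sub) {
    m <- list()
    for (tk in tasks) {
      m[[paste0("face_", tk)]] <-
        setNames(sub$face_prop[sub$task == tk], sub$participant[sub$task == tk])
    }
    up <- stats::aggregate(upper_prop ~ participant, data = sub, FUN = mean,
                           na.action = stats::na.omit)
    m[["upper_face"]] <- setNames(up$upper_prop, up$participant)
    m
  }
  rows <- list()
  for (gr in g) {
    tr_g <- traits[traits$group == gr, , drop = FALSE]
    for (state in c("speaking", "listening")) {
      sub <- d[d$group == gr & d$speech_state == state, , drop = FALSE]
      mets <- metric_table(sub)
      for (mname in names(mets)) {
        vals <- mets[[mname]]
        for (tr in c("aq", "lsas")) {
          tv <- setNames(tr_g[[tr]], tr_g$participant)
          common <- intersect(names(vals)[!is.na(vals)], names(tv))
          if (length(common) < 4) next
          sc <- spearman_cor(tv[common], vals[common])
          rows[[length(rows) + 1]] <- tibble::tibble(
            group = gr, speech_state = state, metric = mname,
            trait = toupper(tr), sc)
        }
      }
    }
  }
  list(group_tests = group_tests, correlations = dplyr::bind_rows(rows))
}

#' Median/IQR summary of proportional looking per condition
#'
#' The descriptive layout used for reporting: medians and interquartile
#' ranges (in percent) of a proportional looking measure per group, task and
#' speech state.
#'
#' @param outcomes output of [compute_proportions()] with a `group` column.
#' @param dependent `"face_prop"` or `"upper_prop"`.
#' @return a tibble: group, task, speech_state, n, median_pct, iqr_pct.
#' @export
roi_summary_table <- function(outcomes, dependent = c("face_prop", "upper_prop")) {
  dependent <- match.arg(dependent)
  d <- outcomes
  d$y <- d[[dependent]]
  if ("missing" %in% names(d)) d$y[d$missing] <- NA
  d |>
    dplyr::group_by(.data$group, .data$task, .data$speech_state) |>
    dplyr::summarise(
      n = sum(!is.na(.data$y)),
      median_pct = 100 * median(.data$y, na.rm = TRUE),
      iqr_pct = 100 * stats::IQR(.data$y, na.rm = TRUE),
      .groups = "drop"
    )
}
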