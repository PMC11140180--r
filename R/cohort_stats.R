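#' Repeated-measures one-way ANOVA
#'
#' Within-subject one-way ANOVA for one variable measured on every animal
#' in every state. The total sum of squares is decomposed into condition,
#' subject and error components; `F = MS_condition / MS_error` with
#' `df1 = k - 1`, `df2 = (k - 1)(n - 1)` for `k` states and `n` animals.
#' Animals missing any state are dropped (complete-case design) with a
#' warning.
#'
#' @param data A data.frame with one row per animal-state combination.
#' @param variable Name of the response column.
#' @param animal,state Names of the subject and condition columns.
#' @return A list with `F`, `df1`, `df2`, `p`, the sums of squares, `n`
#'   (animals used) and a `degenerate` flag (zero error variance).
#' @export
rm_anova <- function(data, variable, animal = "animal_id", state = "state") {
  d <- data[, c(animal, state, variable)]
  names(d) <- c("animal", "state", "y")
  d <- d[stats::complete.cases(d), ]
  states <- unique(d$state)
  k <- length(states)
  counts <- table(d$animal)
  complete <- names(counts)[counts == k]
  if (length(complete) < length(counts))
    warning("dropping ", length(counts) - length(complete),
            " animal(s) without all states", call. = FALSE)
  d <- d[d$animal %in% complete, ]
  n <- length(complete)
  if (n < 2L || k < 2L)
    stop("need >= 2 animals with complete states and >= 2 states",
         call. = FALSE)

  grand <- mean(d$y)
  state_means <- tapply(d$y, d$state, mean)
  animal_means <- tapply(d$y, d$animal, mean)
  ss_cond <- n * sum((state_means - grand)^2)
  ss_subj <- k * sum((animal_means - grand)^2)
  ss_tot <- sum((d$y - grand)^2)
  ss_err <- max(ss_tot - ss_cond - ss_subj, 0)
  df1 <- k - 1L; df2 <- (k - 1L) * (n - 1L)
  degenerate <- ss_err <= 1e-12 * max(ss_tot, 1)
  Fval <- if (degenerate) Inf else (ss_cond / df1) / (ss_err / df2)
  p <- if (degenerate) {
    if (ss_cond <= 1e-12 * max(ss_tot, 1)) NA_real_ else 0
  } else stats::pf(Fval, df1, df2, lower.tail = FALSE)
  list(F = Fval, df1 = df1, df2 = df2, p = p,
       SS_condition = ss_cond, SS_subject = ss_subj, SS_error = ss_err,
       n = n, k = k, degenerate = degenerate)
}

#' Paired t-test with degenerate-difference handling
#'
#' Standard paired t on the within-pair differences. When the differences
#' have zero variance the test statistic is undefined; the result is
#' flagged `degenerate`, with `t = 0, p = 1` for identically zero
#' differences and an infinite `t` (p = 0) for a constant nonzero shift.
#'
#' @param x,y Paired numeric vectors of equal length >= 2.
#' @return A list with `t`, `df`, `p`, `mean_diff` and `degenerate`.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L)
    stop("x and y must have equal length >= 2", call. = FALSE)
  d <- x - y
  if (stats::sd(d) <= 1e-12 * max(abs(d), 1)) {
    md <- mean(d)
    return(list(t = if (md == 0) 0 else Inf * sign(md),
                df = length(d) - 1L, p = if (md == 0) 1 else 0,
                mean_diff = md, degenerate = TRUE))
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_diff = unname(tt$estimate), degenerate = FALSE)
}

#' Bonferroni-corrected pairwise paired comparisons
#'
#' Paired t-test for every pair of states, with Bonferroni adjustment
#' `p_adj = min(1, m p)` where `m` is the number of pairs (3 for three
#' states). Complete cases only, matched within animal.
#'
#' @inheritParams rm_anova
#' @return A data.frame with one row per state pair: `state_a`, `state_b`,
#'   `t`, `df`, `p`, `p_adj`, `degenerate`.
#' @export
bonferroni_pairwise <- function(data, variable, animal = "animal_id",
                                state = "state") {
  d <- data[, c(animal, state, variable)]
  names(d) <- c("animal", "state", "y")
  d <- d[stats::complete.cases(d), ]
  states <- unique(d$state)
  if (length(states) < 2L) stop("need >= 2 states", call. = FALSE)
  pairs <- utils::combn(as.character(states), 2L)
  m <- ncol(pairs)
  res <- lapply(seq_len(m), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    da <- d[d$state == a, ]; db <- d[d$state == b, ]
    common <- intersect(da$animal, db$animal)
    tt <- paired_t(da$y[match(common, da$animal)],
                   db$y[match(common, db$animal)])
    data.frame(state_a = a, state_b = b, t = tt$t, df = tt$df, p = tt$p,
               p_adj = min(1, m * tt$p), degenerate = tt$degenerate,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Compact letter display from pairwise comparisons
#'
#' Greedy insert-and-absorb assignment: groups sharing a letter are not
#' significantly different at `alpha`. Deterministic: letter sets are
#' processed and reported in the given state order.
#'
#' @param pairwise Output of [bonferroni_pairwise()] (uses `p_adj`).
#' @param states Character vector giving the display order of states.
#' @param alpha Significance level on the adjusted p-values.
#' @return Named character vector: letters per state.
#' @export
compact_letters <- function(pairwise, states, alpha = 0.05) {
  sets <- list(states)  # start with one set containing all states
  sig <- pairwise[!is.na(pairwise$p_adj) & pairwise$p_adj < alpha, ,
                  drop = FALSE]
  for (j in seq_len(nrow(sig))) {
    a <- sig$state_a[j]; b <- sig$state_b[j]
    new_sets <- list()
    for (s in sets) {
      if (a %in% s && b %in% s) {
        new_sets <- c(new_sets, list(setdiff(s, a)), list(setdiff(s, b)))
      } else new_sets <- c(new_sets, list(s))
    }
    # absorb sets wholly contained in another
    keep <- rep(TRUE, length(new_sets))
    for (i in seq_along(new_sets)) for (l in seq_along(new_sets)) {
      if (i != l && keep[i] && keep[l] &&
          all(new_sets[[i]] %in% new_sets[[l]])) keep[i] <- FALSE
    }
    sets <- unique(new_sets[keep])
  }
  # order sets by first member's position in `states`
  first_pos <- vapply(sets, function(s) min(match(s, states)), numeric(1))
  sets <- sets[order(first_pos)]
  out <- stats::setNames(rep("", length(states)), states)
  for (i in seq_along(sets)) {
    for (s in sets[[i]]) out[s] <- paste0(out[s], letters[i])
  }
  out
}

#' Table-style cohort summary
#'
#' Per-variable summary in the layout of a physiology results table:
#' mean and SD per state, the repeated-measures ANOVA F and p, and a
#' compact letter display from Bonferroni-adjusted pairwise paired t-tests
#' (states with different letters differ significantly).
#'
#' @inheritParams rm_anova
#' @param variables Character vector of response columns to summarise.
#' @param states State display order; default the order of appearance.
#' @param alpha Significance level.
#' @return A data.frame with one row per variable: `mean_<state>`,
#'   `sd_<state>`, `letters_<state>`, `F`, `df1`, `df2`, `p`.
#' @export
summarize_cohort <- function(data, variables, animal = "animal_id",
                             state = "state", states = NULL, alpha = 0.05) {
  if (is.null(states)) states <- as.character(unique(data[[state]]))
  rows <- lapply(variables, function(v) {
    an <- rm_anova(data, v, animal, state)
    pw <- bonferroni_pairwise(data, v, animal, state)
    lt <- compact_letters(pw, states, alpha)
    mu <- tapply(data[[v]], data[[state]], mean, na.rm = TRUE)[states]
    sdv <- tapply(data[[v]], data[[state]], stats::sd, na.rm = TRUE)[states]
    out <- data.frame(variable = v, F = an$F, df1 = an$df1, df2 = an$df2,
                      p = an$p, stringsAsFactors = FALSE)
    for (s in states) {
      out[[paste0("mean_", s)]] <- unname(mu[s])
      out[[paste0("sd_", s)]] <- unname(sdv[s])
      out[[paste0("letters_", s)]] <- unname(lt[s])
    }
    out
  })
  do.call(rbind, rows)
}

#' Average a time series into fixed-width bins
#'
#' Utility for analysing continuously logged variables (arterial pressure,
#' heart rate) as fixed-width averages (the study uses 5-min bins) before
#' feeding each bin to [rm_anova()].
#'
#' @param time Time stamps (minutes).
#' @param value Measurements at each time stamp.
#' @param width Bin width in minutes (default 5).
#' @return A data.frame with `bin_start` and the bin `mean`.
#' @export
bin_time_average <- function(time, value, width = 5) {
  if (width <= 0) stop("width must be positive", call. = FALSE)
  bin <- floor(time / width) * width
  agg <- tapply(value, bin, mean)
  data.frame(bin_start = as.numeric(names(agg)), mean = as.numeric(agg))
}
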