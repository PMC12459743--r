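#' Code raw responses into behavioral outcomes
#'
#' Applies the task's coding rules: a Go trial is a *hit* when the correct
#' key is pressed within the response window, an *error* when a wrong key is
#' pressed within the window, and a *miss* otherwise. A Nogo trial is a
#' *correct omission* when no response falls inside the window and a *false
#' alarm* when any response does. Outcome counts always partition the trials
#' of each type.
#'
#' @param design a `task_design`.
#' @param responses data frame with `trial_index`, `response`
#'   ("left"/"right"/"none") and `rt_ms` (NA when none), timed relative to
#'   stimulus onset.
#' @param response_window_ms coding window (default 1700 ms).
#' @return data frame of class `behavioral_records`: `trial_index`,
#'   `response`, `rt_ms`, `outcome`.
#' @export
code_responses <- function(design, responses, response_window_ms = 1700) {
  stopifnot(inherits(design, "task_design"))
  if (nrow(responses) && any(!(responses$trial_index %in% design$index)))
    stop("response refers to a trial not in the design")
  m <- merge(as.data.frame(design), responses, by.x = "index",
             by.y = "trial_index", all.x = TRUE, sort = TRUE)
  m <- m[order(m$index), ]
  resp <- ifelse(is.na(m$response), "none", m$response)
  in_window <- resp != "none" & !is.na(m$rt_ms) &
    m$rt_ms >= 0 & m$rt_ms <= response_window_ms
  outcome <- character(nrow(m))
  go <- m$trial_type == "Go"
  outcome[go & in_window & resp == m$correct_response] <- "hit"
  outcome[go & in_window & resp != m$correct_response] <- "error"
  outcome[go & !in_window] <- "miss"
  outcome[!go & in_window] <- "false_alarm"
  outcome[!go & !in_window] <- "correct_omission"
  out <- data.frame(trial_index = m$index, response = resp,
                    rt_ms = ifelse(in_window, m$rt_ms, NA_real_),
                    outcome = outcome)
  structure(out, class = c("behavioral_records", "data.frame"))
}

#' Per-condition accuracy table
#'
#' Accuracy is the hit rate on Go cells and the correct-omission rate on
#' Nogo cells, for each trial-type x congruency cell.
#'
#' @param records a `behavioral_records`.
#' @param design the matching `task_design`.
#' @return data frame with `trial_type`, `congruency`, `n`, `n_correct`,
#'   `accuracy` (NA and `undefined = TRUE` for empty cells).
#' @export
accuracy_table <- function(records, design) {
  stopifnot(inherits(records, "behavioral_records"),
            inherits(design, "task_design"))
  m <- merge(as.data.frame(design), as.data.frame(records),
             by.x = "index", by.y = "trial_index")
  cells <- expand.grid(trial_type = c("Go", "Nogo"),
                       congruency = c("congruent", "incongruent"),
                       stringsAsFactors = FALSE)
  cells$n <- NA_integer_; cells$n_correct <- NA_integer_
  cells$accuracy <- NA_real_; cells$undefined <- FALSE
  for (r in seq_len(nrow(cells))) {
    sel <- m$trial_type == cells$trial_type[r] &
      m$congruency == cells$congruency[r]
    cells$n[r] <- sum(sel)
    good <- if (cells$trial_type[r] == "Go") "hit" else "correct_omission"
    cells$n_correct[r] <- sum(m$outcome[sel] == good)
    if (cells$n[r] > 0) cells$accuracy[r] <- cells$n_correct[r] / cells$n[r]
    else cells$undefined[r] <- TRUE
  }
  cells
}

#' Simon Nogo effect
#'
#' Accuracy on congruent Nogo trials minus accuracy on incongruent Nogo
#' trials. On Nogo trials the usual congruency advantage inverts (the
#' congruent stimulus primes the prepotent response that must be withheld),
#' so the effect is typically negative; a smaller magnitude indicates less
#' interference from response automaticity.
#'
#' @param acc an accuracy table from [accuracy_table()].
#' @return scalar effect, or NA (with a warning) if either Nogo cell is
#'   undefined.
#' @export
simon_nogo_effect <- function(acc) {
  gc <- acc[acc$trial_type == "Nogo" & acc$congruency == "congruent", ]
  gi <- acc[acc$trial_type == "Nogo" & acc$congruency == "incongruent", ]
  if (!nrow(gc) || !nrow(gi) || gc$undefined || gi$undefined) {
    warning("Nogo cell undefined; Simon Nogo effect is NA")
    return(NA_real_)
  }
  gc$accuracy - gi$accuracy
}

#' Paired test for asymmetry between the two directions of an edge
#'
#' Two-sided paired Wilcoxon signed-rank test on per-subject connectivity
#' values for i -> j against j -> i. The reported direction is the one with
#' the larger mean.
#'
#' @param ij,ji per-subject values for the two directions (paired).
#' @param alpha significance level (default 0.05).
#' @return list with `p`, `direction` (`"ij"`, `"ji"` or `"none"`),
#'   `significant`.
#' @export
direction_asymmetry_test <- function(ij, ji, alpha = 0.05) {
  stopifnot(length(ij) == length(ji))
  n <- length(ij)
  if (n < 6)
    stop("need at least 6 paired subjects for the signed-rank test; got ", n)
  if (all(ij == ji))
    return(list(p = 1, direction = "none", significant = FALSE))
  p <- suppressWarnings(stats::wilcox.test(ij, ji, paired = TRUE,
                                           exact = NULL)$p.value)
  dir <- if (mean(ij) > mean(ji)) "ij" else if (mean(ij) < mean(ji)) "ji" else "none"
  list(p = p, direction = dir, significant = p < alpha)
}

#' Network strength (average connectivity)
#'
#' The mean of all connections of a connectivity matrix. Self-connections
#' are excluded by default.
#'
#' @param conn a `connectivity_result` or an M x M matrix.
#' @param kind which matrix to use for a `connectivity_result` ("LC"/"NC").
#' @param include_self include diagonal entries (default FALSE).
#' @return scalar mean connectivity.
#' @export
network_strength <- function(conn, kind = c("LC", "NC"), include_self = FALSE) {
  m <- if (inherits(conn, "connectivity_result")) conn[[match.arg(kind)]] else conn
  stopifnot(is.matrix(m), nrow(m) == ncol(m), nrow(m) >= 2)
  if (include_self) mean(m) else mean(m[row(m) != col(m)])
}

#' Compare network strength between two samples
#'
#' Nonparametric two-sided comparison: Wilcoxon signed-rank for paired
#' samples (e.g., two conditions within a group), rank-sum (Mann-Whitney)
#' for independent samples (two groups).
#'
#' @param a,b numeric vectors of per-subject strengths.
#' @param paired logical.
#' @return list with `p`, `statistic`, `method`.
#' @export
compare_strength <- function(a, b, paired = FALSE) {
  if (length(a) < 3 || length(b) < 3)
    stop("need at least 3 values per sample")
  if (paired && length(a) != length(b))
    stop("paired comparison requires equal lengths")
  if (paired && all(a == b)) return(list(p = 1, statistic = NA_real_,
                                         method = "Wilcoxon signed rank"))
  w <- suppressWarnings(stats::wilcox.test(a, b, paired = paired))
  list(p = w$p.value, statistic = unname(w$statistic), method = w$method)
}
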