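#' Generate a Simon Go/Nogo task design
#'
#' Builds the trial sequence of a lateralized Go/Nogo task with a Simon-type
#' congruency manipulation. Every block contains exactly the same number of
#' trials from each trial-type x congruency cell; the order within a block is
#' randomized. On congruent trials the stimulus appears on the side of the
#' required response hand, on incongruent trials on the opposite side. Nogo
#' trials require no response.
#'
#' @param n_trials total number of trials (default 720).
#' @param go_fraction fraction of Go trials (default 0.7).
#' @param congruent_fraction fraction of congruent trials within each trial
#'   type (default 0.5).
#' @param n_blocks number of blocks (default 6); must divide `n_trials`.
#' @param iti_range_ms closed interval for the uniform inter-trial interval,
#'   in ms (default `c(1300, 1700)`).
#' @param seed integer seed controlling trial order and ITIs.
#' @return A data frame of class `task_design` with columns `index`, `block`,
#'   `trial_type`, `congruency`, `stimulus_side`, `correct_response`, `iti_ms`.
#' @examples
#' d <- generate_task_design(seed = 1)
#' table(d$trial_type)          # 504 Go / 216 Nogo
#' @export
generate_task_design <- function(n_trials = 720, go_fraction = 0.7,
                                 congruent_fraction = 0.5, n_blocks = 6,
                                 iti_range_ms = c(1300, 1700), seed = 1) {
  stopifnot(n_trials >= 0, go_fraction >= 0, go_fraction <= 1,
            congruent_fraction >= 0, congruent_fraction <= 1,
            n_blocks >= 1, length(iti_range_ms) == 2,
            iti_range_ms[1] <= iti_range_ms[2])
  empty <- data.frame(index = integer(), block = integer(),
                      trial_type = character(), congruency = character(),
                      stimulus_side = character(), correct_response = character(),
                      iti_ms = numeric())
  if (n_trials == 0) return(structure(empty, class = c("task_design", "data.frame")))
  if (n_trials %% n_blocks != 0)
    stop("n_trials (", n_trials, ") is not divisible by n_blocks (", n_blocks, ")")

  per_block <- n_trials / n_blocks
  cells <- expand.grid(trial_type = c("Go", "Nogo"),
                       congruency = c("congruent", "incongruent"),
                       stringsAsFactors = FALSE)
  type_frac <- c(Go = go_fraction, Nogo = 1 - go_fraction)
  cong_frac <- c(congruent = congruent_fraction,
                 incongruent = 1 - congruent_fraction)
  cells$n <- per_block * type_frac[cells$trial_type] * cong_frac[cells$congruency]
  bad <- abs(cells$n - round(cells$n)) > 1e-9
  if (any(bad)) {
    b <- which(bad)[1]
    stop(sprintf("per-block count for cell %s/%s is not an integer (%g)",
                 cells$trial_type[b], cells$congruency[b], cells$n[b]))
  }
  cells$n <- as.integer(round(cells$n))

  set.seed(seed)
  blocks <- lapply(seq_len(n_blocks), function(b) {
    tt <- rep(cells$trial_type, cells$n)
    cg <- rep(cells$congruency, cells$n)
    ord <- sample.int(length(tt))
    tt <- tt[ord]; cg <- cg[ord]
    # response hand assigned by the letter identity, balanced at random;
    # stimulus side then follows from the congruency cell
    hand <- sample(c("left", "right"), length(tt), replace = TRUE)
    side <- ifelse(cg == "congruent", hand,
                   ifelse(hand == "left", "right", "left"))
    data.frame(block = b, trial_type = tt, congruency = cg,
               stimulus_side = side,
               correct_response = ifelse(tt == "Go", hand, "none"),
               iti_ms = stats::runif(length(tt), iti_range_ms[1], iti_range_ms[2]))
  })
  out <- do.call(rbind, blocks)
  out <- cbind(index = seq_len(nrow(out)), out)
  structure(out, class = c("task_design", "data.frame"))
}

#' Simulate behavioral responses for a task design
#'
#' Draws per-trial responses with condition-dependent accuracy and a Simon
#' reaction-time cost on incongruent Go trials. Go trials are answered
#' correctly with the cell's probability; otherwise the wrong key is pressed
#' or the response is omitted (equal odds). Nogo responses (false alarms)
#' occur with one minus the cell's probability. Reaction times are Gaussian,
#' truncated to the response window.
#'
#' @param design a `task_design`.
#' @param p_correct named numeric vector of per-cell correct probabilities
#'   with names `go_congruent`, `go_incongruent`, `nogo_congruent`,
#'   `nogo_incongruent`.
#' @param rt_model list with `mean_ms`, `sd_ms` and `simon_shift_ms` (the RT
#'   cost added on incongruent Go trials).
#' @param seed integer seed.
#' @param response_window_ms response-coding window (default 1700 ms).
#' @return A data frame of class `behavioral_records` with columns
#'   `trial_index`, `response`, `rt_ms` (NA when no response) and `outcome`.
#' @export
simulate_behavior <- function(design,
                              p_correct = c(go_congruent = 0.97,
                                            go_incongruent = 0.93,
                                            nogo_congruent = 0.85,
                                            nogo_incongruent = 0.91),
                              rt_model = list(mean_ms = 450, sd_ms = 100,
                                              simon_shift_ms = 30),
                              seed = 1, response_window_ms = 1700) {
  stopifnot(inherits(design, "task_design"))
  needed <- c("go_congruent", "go_incongruent", "nogo_congruent", "nogo_incongruent")
  extra <- setdiff(names(p_correct), needed)
  if (length(extra)) stop("unknown condition key(s): ", paste(extra, collapse = ", "))
  if (!all(needed %in% names(p_correct)))
    stop("p_correct must name all four cells: ", paste(needed, collapse = ", "))
  stopifnot(all(p_correct >= 0 & p_correct <= 1), rt_model$sd_ms > 0)

  n <- nrow(design)
  if (n == 0) {
    return(code_responses(design, data.frame(trial_index = integer(),
                                             response = character(),
                                             rt_ms = numeric())))
  }
  set.seed(seed)
  key <- paste0(tolower(design$trial_type), "_", design$congruency)
  p <- unname(p_correct[key])
  correct <- stats::runif(n) < p

  response <- rep("none", n)
  is_go <- design$trial_type == "Go"
  # correct Go -> required key; incorrect Go -> wrong key or omission
  response[is_go & correct] <- design$correct_response[is_go & correct]
  go_bad <- which(is_go & !correct)
  if (length(go_bad)) {
    press_wrong <- stats::runif(length(go_bad)) < 0.5
    wrong <- ifelse(design$correct_response[go_bad] == "left", "right", "left")
    response[go_bad[press_wrong]] <- wrong[press_wrong]
  }
  # incorrect Nogo -> false alarm with a random key
  nogo_bad <- which(!is_go & !correct)
  if (length(nogo_bad))
    response[nogo_bad] <- sample(c("left", "right"), length(nogo_bad), replace = TRUE)

  rt <- rep(NA_real_, n)
  responded <- response != "none"
  mu <- rt_model$mean_ms +
    ifelse(is_go & design$congruency == "incongruent", rt_model$simon_shift_ms, 0)
  if (any(responded)) {
    draw <- stats::rnorm(sum(responded), mu[responded], rt_model$sd_ms)
    rt[responded] <- pmin(pmax(draw, 1), response_window_ms)
  }
  responses <- data.frame(trial_index = design$index, response = response, rt_ms = rt)
  code_responses(design, responses, response_window_ms = response_window_ms)
}

#' Write / read a task design as CSV
#' @param design a `task_design`.
#' @param path file path.
#' @export
write_task_design <- function(design, path) {
  stopifnot(inherits(design, "task_design"))
  utils::write.csv(as.data.frame(design), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_task_design
#' @export
read_task_design <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  structure(d, class = c("task_design", "data.frame"))
}
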