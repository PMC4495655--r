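#' Simulated dichoptic observer configuration
#'
#' The observer model for the dichoptic brightness-matching task. Retinal
#' and cortical gain suppressions are multiplicative and act in series on
#' the perceived brightness of the test flash at the adapted location: the
#' cortical gain applies regardless of which eye received the adapt flash,
#' the retinal gain only when adapt and test share an eye. The observer
#' adjusts a spatially offset comparison flash toward perceived equality
#' with multiplicative Gaussian judgment noise.
#'
#' Step sizes are expressed as fractions of the observer's initial percept
#' of the reference flash, which makes the whole staircase scale-equivariant
#' in the perceived target: the same relative geometry unfolds whatever the
#' suppression, so in the noise-free limit the recovered interaction index
#' equals `1 - retinal_suppression` exactly and the cortical gain cancels.
#'
#' @param retinal_suppression Multiplicative same-eye gain in (0, 1].
#' @param cortical_suppression Multiplicative binocular gain in (0, 1].
#' @param judgment_noise_sd SD of the multiplicative judgment noise, as a
#'   fraction of perceived intensity (>= 0).
#' @param initial_step Initial adjustment increment as a fraction of the
#'   perceived reference (> 0).
#' @param start_frac Starting intensity of the adjustable flash as a
#'   fraction of the perceived reference.
#' @param n_crossings Number of direction reversals at which a trial
#'   completes (default 6).
#' @param seed Default integer seed for trials.
#' @return An object of class `"observer_config"`.
#' @export
observer_config <- function(retinal_suppression = 0.6,
                            cortical_suppression = 0.85,
                            judgment_noise_sd = 0.05,
                            initial_step = 0.15,
                            start_frac = 0.6,
                            n_crossings = 6L,
                            seed = 1L) {
  for (g in c(retinal_suppression, cortical_suppression)) {
    if (!is.numeric(g) || g <= 0 || g > 1) {
      stop("suppression gains must lie in (0, 1]", call. = FALSE)
    }
  }
  if (judgment_noise_sd < 0) stop("`judgment_noise_sd` must be >= 0",
                                  call. = FALSE)
  stopifnot_scalar(initial_step, "initial_step", positive = TRUE)
  stopifnot_scalar(start_frac, "start_frac", positive = TRUE)
  if (n_crossings < 2) stop("`n_crossings` must be >= 2", call. = FALSE)
  structure(list(retinal_suppression = retinal_suppression,
                 cortical_suppression = cortical_suppression,
                 judgment_noise_sd = judgment_noise_sd,
                 initial_step = initial_step,
                 start_frac = start_frac,
                 n_crossings = as.integer(n_crossings),
                 seed = as.integer(seed)),
            class = "observer_config")
}

#' Simulate one adjustment staircase trial
#'
#' The observer repeatedly compares the perceived brightness of the
#' adapted-location test flash (suppressed by the configured gains) with the
#' adjustable flash and steps the adjustable intensity toward perceived
#' equality. Each direction reversal is a crossing; the adjustment increment
#' shrinks by 1/3 after each crossing (floored at the minimum permissible
#' increment, `initial_step * (2/3)^8`), and the trial completes at
#' `n_crossings` crossings.
#'
#' @param observer An [observer_config()].
#' @param condition Condition label (e.g. `"rod_cone_short"`), carried as
#'   metadata.
#' @param eye_mode `"same"` (adapt and test in one eye: retinal and
#'   cortical suppression) or `"separate"` (cortical only).
#' @param true_reference Physical intensity of the reference test flash
#'   (> 0).
#' @param seed Integer seed; defaults to the observer's.
#' @return An object of class `"staircase_trial"`: adjustments, crossings
#'   (value and the step size in force before each crossing), completion
#'   flag and metadata.
#' @export
simulate_observer_trial <- function(observer, condition = "rod_cone_short",
                                    eye_mode = c("same", "separate"),
                                    true_reference = 1, seed = NULL) {
  stopifnot(inherits(observer, "observer_config"))
  eye_mode <- match.arg(eye_mode)
  stopifnot_scalar(true_reference, "true_reference", positive = TRUE)
  if (is.null(seed)) seed <- observer$seed

  target <- true_reference * observer$cortical_suppression *
    (if (eye_mode == "same") observer$retinal_suppression else 1)

  res <- with_seed(seed, {
    noisy <- function() target * (1 + if (observer$judgment_noise_sd > 0)
      stats::rnorm(1, sd = observer$judgment_noise_sd) else 0)
    percept0 <- noisy()
    step0 <- observer$initial_step * percept0
    floor_step <- step0 * (2 / 3)^8
    x <- observer$start_frac * percept0
    step <- step0
    dir_prev <- NA_integer_
    k <- 0L
    xs <- numeric(0)
    dirs <- integer(0)
    cross_val <- numeric(0)
    cross_step <- numeric(0)
    completed <- FALSE
    for (it in seq_len(1000L)) {
      dir <- if (x < noisy()) 1L else -1L
      if (!is.na(dir_prev) && dir != dir_prev) {
        k <- k + 1L
        cross_val <- c(cross_val, x)
        cross_step <- c(cross_step, step)
        step <- max(step0 * (2 / 3)^k, floor_step)
        if (k >= observer$n_crossings) { completed <- TRUE; break }
      }
      x <- x + dir * step
      xs <- c(xs, x)
      dirs <- c(dirs, dir)
      dir_prev <- dir
    }
    list(xs = xs, dirs = dirs, cross_val = cross_val,
         cross_step = cross_step, completed = completed)
  })

  structure(list(condition = condition, eye_mode = eye_mode,
                 true_reference = true_reference,
                 adjustments = data.frame(intensity = res$xs,
                                          direction = res$dirs),
                 crossings = data.frame(value = res$cross_val,
                                        step = res$cross_step),
                 completed = res$completed,
                 seed = seed),
            class = "staircase_trial")
}

#' @export
print.staircase_trial <- function(x, ...) {
  cat(sprintf(
    "<staircase_trial> %s / %s eye: %d adjustments, %d crossings%s\n",
    x$condition, x$eye_mode, nrow(x$adjustments), nrow(x$crossings),
    if (x$completed) "" else " (incomplete)"))
  invisible(x)
}

#' Match estimate from a staircase trial
#'
#' The crossing-weighted match (task v2): midpoints of contiguous pairs of
#' crossing values, each weighted by the inverse of the adjustment step in
#' force between that pair, averaged. The alternative `"final_bracket"`
#' method (task v1's manual match, simulated) is the midpoint of the last
#' two crossings.
#'
#' @param trial A `"staircase_trial"`.
#' @param method `"weighted"` (default) or `"final_bracket"`.
#' @return An object of class `"match_result"`: `matched_intensity`,
#'   `n_crossings`, `method`.
#' @examples
#' # two crossing pairs: midpoints 6 and 5, weights 1/3 and 1/2 -> 5.4
#' tr <- structure(list(
#'   crossings = data.frame(value = c(9, 3, 7), step = c(3, 3, 2)),
#'   completed = TRUE), class = "staircase_trial")
#' staircase_match(tr)$matched_intensity
#' @export
staircase_match <- function(trial, method = c("weighted", "final_bracket")) {
  stopifnot(inherits(trial, "staircase_trial"))
  method <- match.arg(method)
  cr <- trial$crossings
  n <- nrow(cr)
  if (n < 2L) {
    stop(structure(class = c("rodcone_exclusion", "error", "condition"),
                   list(message = "trial excluded: fewer than 2 crossings",
                        call = sys.call())))
  }
  if (method == "weighted") {
    # step in force between crossings k and k+1 is the step recorded at
    # crossing k+1 (the increment set after crossing k)
    mids <- (cr$value[-n] + cr$value[-1L]) / 2
    w <- 1 / cr$step[-1L]
    match_val <- sum(w * mids) / sum(w)
  } else {
    match_val <- (cr$value[n - 1L] + cr$value[n]) / 2
  }
  structure(list(matched_intensity = match_val, n_crossings = n,
                 method = method),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> %.5g (%d crossings, %s)\n",
              x$matched_intensity, x$n_crossings, x$method))
  invisible(x)
}

#' Apply the trial and condition exclusion rules
#'
#' Version v1 drops trials with fewer than 2 crossings and invalidates any
#' condition (condition x eye mode cell) left with 3 or fewer trials.
#' Version v2 keeps trials that completed their 6 crossings.
#'
#' @param trials A list of `"staircase_trial"`s.
#' @param version `"v1"` or `"v2"`.
#' @return A list with `kept` (the surviving trials) and `validity` (a
#'   data.frame with one row per condition x eye mode: trial counts before
#'   and after exclusion and a `valid` flag).
#' @export
apply_exclusions <- function(trials, version = c("v2", "v1")) {
  version <- match.arg(version)
  stopifnot(all(vapply(trials, inherits, TRUE, "staircase_trial")))
  keep <- if (version == "v1") {
    vapply(trials, function(tr) nrow(tr$crossings) >= 2L, TRUE)
  } else {
    vapply(trials, function(tr) isTRUE(tr$completed), TRUE)
  }
  kept <- trials[keep]

  key <- function(ts) paste(vapply(ts, `[[`, "", "condition"),
                            vapply(ts, `[[`, "", "eye_mode"), sep = "|")
  all_keys <- key(trials)
  kept_keys <- key(kept)
  cells <- unique(all_keys)
  n_before <- vapply(cells, function(k) sum(all_keys == k), 0L)
  n_after <- vapply(cells, function(k) sum(kept_keys == k), 0L)
  valid <- if (version == "v1") n_after > 3L else n_after > 0L
  parts <- strsplit(cells, "|", fixed = TRUE)
  validity <- data.frame(
    condition = vapply(parts, `[[`, "", 1L),
    eye_mode = vapply(parts, `[[`, "", 2L),
    n_before = n_before, n_after = n_after, valid = valid,
    row.names = NULL
  )
  if (version == "v1") {
    ok_cells <- cells[valid]
    kept <- kept[kept_keys %in% ok_cells]
  }
  list(kept = kept, validity = validity)
}

#' Perceptual interaction index
#'
#' `II = 1 - S_1eye / S_2eye`, where `S_1eye` is the sensitivity ratio
#' (mean matched intensity over the reference intensity) for same-eye
#' delivery and `S_2eye` for separate-eye delivery. The index is 0 when
#' one- and two-eye interactions are equally strong, and 1 when the adapt
#' flash completely suppresses perception of the test flash for one- but
#' not two-eye delivery. Because retinal and cortical gains multiply in
#' series, any purely cortical (binocular) suppression cancels in the
#' ratio.
#'
#' @param same_eye_matches,separate_eye_matches Numeric vectors of matched
#'   intensities (non-empty).
#' @param reference The reference intensity (> 0).
#' @return An object of class `"perceptual_interaction_result"`: `S_1eye`,
#'   `S_2eye`, `II`.
#' @export
perceptual_interaction_index <- function(same_eye_matches,
                                         separate_eye_matches,
                                         reference = 1) {
  if (length(same_eye_matches) == 0L || length(separate_eye_matches) == 0L) {
    stop("both match vectors must be non-empty", call. = FALSE)
  }
  stopifnot_scalar(reference, "reference", positive = TRUE)
  s1 <- mean(same_eye_matches) / reference
  s2 <- mean(separate_eye_matches) / reference
  if (s2 == 0) stop("S_2eye is zero; interaction index undefined",
                    call. = FALSE)
  structure(list(S_1eye = s1, S_2eye = s2, II = 1 - s1 / s2),
            class = "perceptual_interaction_result")
}

#' @export
print.perceptual_interaction_result <- function(x, ...) {
  cat(sprintf(
    "<perceptual_interaction_result> II = %.4f (S_1eye = %.4g, S_2eye = %.4g)\n",
    x$II, x$S_1eye, x$S_2eye))
  invisible(x)
}

#' Simulate a full matching session
#'
#' Runs interleaved same-eye and separate-eye staircase trials for each
#' condition, applies the exclusion rules, estimates matches, and computes
#' the per-condition perceptual interaction index. The per-condition
#' retinal suppressions encode how strongly the adapt flash suppresses the
#' test percept in that condition (e.g. rod-adapt/cone-test at a short
#' offset suppresses strongly; at a long offset hardly at all).
#'
#' @param observer An [observer_config()]; its `retinal_suppression` is
#'   overridden per condition.
#' @param conditions Named numeric vector mapping condition labels to
#'   retinal suppression gains.
#' @param n_trials Trials per condition and eye mode (default 12).
#' @param reference Reference intensity (default 1).
#' @param version Task version for exclusions/matching (default `"v2"`).
#' @param seed Root seed for the session.
#' @return An object of class `"session_summary"`: a data.frame with one
#'   row per condition (mean matches, trial counts and II) plus the kept
#'   trials as an attribute.
#' @export
simulate_session <- function(observer,
                             conditions = c(rod_cone_short = 0.6,
                                            rod_cone_long = 0.95,
                                            cone_rod_short = 0.9),
                             n_trials = 12, reference = 1,
                             version = c("v2", "v1"), seed = 1) {
  stopifnot(inherits(observer, "observer_config"))
  version <- match.arg(version)
  if (is.null(names(conditions)) || any(names(conditions) == "")) {
    stop("`conditions` must be a named vector of retinal suppressions",
         call. = FALSE)
  }

  trials <- list()
  idx <- 0L
  for (ci in seq_along(conditions)) {
    obs_c <- observer
    obs_c$retinal_suppression <- conditions[[ci]]
    for (mode in c("same", "separate")) {
      for (k in seq_len(n_trials)) {
        idx <- idx + 1L
        trial_seed <- (derive_seed(seed, "observer") + 613L * idx) %%
          2147483587L
        trials[[idx]] <- simulate_observer_trial(
          obs_c, condition = names(conditions)[ci], eye_mode = mode,
          true_reference = reference, seed = trial_seed)
      }
    }
  }

  ex <- apply_exclusions(trials, version = version)
  match_method <- if (version == "v1") "final_bracket" else "weighted"
  rows <- lapply(names(conditions), function(cond) {
    sub <- Filter(function(tr) tr$condition == cond, ex$kept)
    same <- Filter(function(tr) tr$eye_mode == "same", sub)
    sep <- Filter(function(tr) tr$eye_mode == "separate", sub)
    m_same <- vapply(same, function(tr)
      staircase_match(tr, match_method)$matched_intensity, 0)
    m_sep <- vapply(sep, function(tr)
      staircase_match(tr, match_method)$matched_intensity, 0)
    ii <- if (length(m_same) > 0L && length(m_sep) > 0L) {
      perceptual_interaction_index(m_same, m_sep, reference)$II
    } else NA_real_
    data.frame(condition = cond,
               mean_match_same = if (length(m_same)) mean(m_same) else NA_real_,
               mean_match_separate = if (length(m_sep)) mean(m_sep) else NA_real_,
               n_same = length(m_same), n_separate = length(m_sep),
               II = ii)
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("session_summary", "data.frame"),
            trials = ex$kept, validity = ex$validity, version = version)
}

#' @export
print.session_summary <- function(x, ...) {
  cat(sprintf("Matching session (%s): %d conditions\n",
              attr(x, "version"), nrow(x)))
  NextMethod()
}
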