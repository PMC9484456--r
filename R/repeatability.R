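#' Intraclass correlation (repeatability) of repeated measures
#'
#' One-way ANOVA intraclass correlation, ICC(1):
#' `R = (MS_between - MS_within) / (MS_between + (k - 1) * MS_within)`
#' with `k` the harmonic-mean number of events per individual. The
#' proportion of total variance attributable to differences among
#' individuals. Negative estimates are clamped to 0 (and estimates above 1
#' to 1) with a warning.
#'
#' @param values numeric measurements.
#' @param id grouping factor: the individual each value belongs to.
#' @param n_boot if > 0, a nonparametric bootstrap (resampling individuals
#'   with replacement) attaches a 95% CI as attribute `"ci"`.
#' @return The repeatability estimate in \[0, 1\] (`NaN` with a warning if
#'   there is no variance at all).
#' @examples
#' icc(c(0, 0, 10, 10), c("a", "a", "b", "b"))  # 1
#' @export
icc <- function(values, id, n_boot = 0) {
  id <- as.factor(id)
  keep <- is.finite(values) & !is.na(id)
  values <- values[keep]
  id <- droplevels(id[keep])
  k_i <- table(id)
  if (nlevels(id) < 2) stop("icc needs >= 2 individuals", call. = FALSE)
  if (all(k_i < 2)) {
    stop("icc needs repeated events for at least some individuals ",
         "(all individuals have a single event)", call. = FALSE)
  }
  est <- icc_point(values, id)
  if (n_boot > 0) {
    ids <- levels(id)
    split_v <- split(values, id)
    boots <- vapply(seq_len(n_boot), function(b) {
      take <- sample(ids, length(ids), replace = TRUE)
      v <- unlist(split_v[take], use.names = FALSE)
      g <- factor(rep(seq_along(take), lengths(split_v[take])))
      if (nlevels(g) < 2 || all(table(g) < 2)) return(NA_real_)
      suppressWarnings(icc_point(v, g))
    }, numeric(1))
    attr(est, "ci") <- stats::quantile(boots, c(0.025, 0.975), na.rm = TRUE)
  }
  est
}

icc_point <- function(values, id) {
  k_i <- as.numeric(table(id))
  a <- length(k_i)
  n <- length(values)
  gm <- mean(values)
  mu_i <- tapply(values, id, mean)
  ssb <- sum(k_i * (mu_i - gm)^2)
  ssw <- sum((values - mu_i[id])^2)
  msb <- ssb / (a - 1)
  msw <- ssw / (n - a)
  k_bar <- a / sum(1 / k_i)  # harmonic mean events per individual
  if (msb == 0 && msw == 0) {
    warning("no variance in the data; repeatability undefined")
    return(NaN)
  }
  r <- (msb - msw) / (msb + (k_bar - 1) * msw)
  if (r < 0) {
    warning("negative repeatability estimate clamped to 0")
    r <- 0
  }
  if (r > 1) {
    warning("repeatability estimate above 1 clamped to 1")
    r <- 1
  }
  r
}

#' Repeatability of area under the response curve
#'
#' Per-event AUC (ground or increase mode) computed from one of three
#' point sets, then repeatability across events within individuals:
#' * `"full_curve"`: the full stored minute-resolution event curve,
#' * `"observed_points"`: only the measured (downsampled, noisy) values,
#' * `"windowed_curve"`: the full curve restricted to the time window
#'   spanned by that event's observed samples.
#'
#' @param dataset an `observed_dataset` from [simulate_dataset()], or (for
#'   `basis = "observed_points"` only) any long table with columns
#'   `individual_id`, `event_id`, `time_min`, `value`.
#' @param mode `"ground"` or `"increase"`, see [auc()].
#' @param basis `"full_curve"`, `"observed_points"` or `"windowed_curve"`.
#' @return Repeatability estimate in \[0, 1\].
#' @export
auc_repeatability <- function(dataset, mode = c("ground", "increase"),
                              basis = c("full_curve", "observed_points",
                                        "windowed_curve")) {
  mode <- match.arg(mode)
  basis <- match.arg(basis)
  if (!inherits(dataset, "observed_dataset")) {
    if (basis != "observed_points") {
      stop("basis '", basis, "' needs stored event curves; supply an ",
           "observed_dataset", call. = FALSE)
    }
    obs <- tibble::as_tibble(dataset)
    check_long_format(obs)
    key <- dplyr::distinct(obs, individual_id, event_id)
  } else {
    obs <- dataset$observed
    key <- dataset$curve_key
  }
  aucs <- vapply(seq_len(nrow(key)), function(r) {
    rows <- obs$individual_id == key$individual_id[r] &
      obs$event_id == key$event_id[r]
    t_obs <- obs$time_min[rows]
    v_obs <- obs$value[rows]
    o <- order(t_obs)
    t_obs <- t_obs[o]; v_obs <- v_obs[o]
    if (basis == "observed_points") {
      if (length(t_obs) < 2) {
        stop("event (individual ", key$individual_id[r], ", event ",
             key$event_id[r], ") has fewer than 2 observed points",
             call. = FALSE)
      }
      return(auc(t_obs, v_obs, mode = mode))
    }
    grid <- dataset$grid
    vals <- dataset$curves[r, ]
    if (basis == "full_curve") return(auc(grid, vals, mode = mode))
    ## windowed: restrict curve to [min obs time, max obs time]
    w <- range(t_obs)
    if (diff(w) <= 0) {
      stop("event (individual ", key$individual_id[r], ", event ",
           key$event_id[r], ") spans a zero-width window", call. = FALSE)
    }
    tt <- unique(c(w[1], grid[grid > w[1] & grid < w[2]], w[2]))
    auc(tt, stats::approx(grid, vals, xout = tt)$y, mode = mode)
  }, numeric(1))
  icc(aucs, key$individual_id)
}

#' Profile repeatability of whole response profiles
#'
#' A variance-component summary of whole-profile consistency for datasets
#' where every event is sampled at the same fixed times. `V_w` is the mean
#' (over individuals) of the per-timepoint within-individual variance
#' averaged across timepoints; `V_a` is the across-individual variance of
#' time-specific individual means, averaged across timepoints, minus the
#' within-individual contribution those means retain (`V_w / k` for `k`
#' events, the usual variance-components correction; without it the ratio
#' would sit near `1/(1+k)` instead of 0 for completely unrepeatable
#' profiles). Returns `V_a / (V_a + V_w)`, clamping `V_a` at 0.
#'
#' @param dataset an `observed_dataset` or long table with columns
#'   `individual_id`, `event_id`, `time_min`, `value`; all events must
#'   share the same time grid and some individuals need >= 2 events.
#' @return Profile repeatability in \[0, 1\] (`NaN` with a warning when
#'   all profiles are identical).
#' @export
profile_repeatability <- function(dataset) {
  obs <- if (inherits(dataset, "observed_dataset")) dataset$observed
         else tibble::as_tibble(dataset)
  check_long_format(obs)
  tl <- lapply(split(obs$time_min,
                     interaction(obs$individual_id, obs$event_id, drop = TRUE)),
               function(t) sort(round(t, 9)))
  if (length(unique(tl)) != 1) {
    stop("profile repeatability requires every event sampled at the same ",
         "fixed times", call. = FALSE)
  }
  events_per_ind <- tapply(obs$event_id, obs$individual_id,
                           function(e) length(unique(e)))
  if (all(events_per_ind < 2)) {
    stop("profile repeatability needs repeated events for some individuals",
         call. = FALSE)
  }
  ## within: per individual, variance across events at each timepoint
  wi <- tapply(seq_len(nrow(obs)), obs$individual_id, function(ix) {
    d <- obs[ix, ]
    if (length(unique(d$event_id)) < 2) return(NA_real_)
    mean(tapply(d$value, round(d$time_min, 9), stats::var))
  })
  v_w <- mean(wi, na.rm = TRUE)
  ## among: per timepoint, variance across individuals of individual means,
  ## less the within contribution those means retain (V_w / k events)
  ind_means <- stats::aggregate(value ~ individual_id + time_min, data = obs,
                                FUN = mean)
  v_a_raw <- mean(tapply(ind_means$value, round(ind_means$time_min, 9),
                         stats::var))
  k_bar <- length(events_per_ind) / sum(1 / events_per_ind)
  v_a <- max(0, v_a_raw - v_w / k_bar)
  if (v_a + v_w == 0 || !is.finite(v_a + v_w)) {
    warning("no variance among or within profiles; profile repeatability ",
            "undefined")
    return(NaN)
  }
  v_a / (v_a + v_w)
}

#' Full repeatability report for a simulated or field dataset
#'
#' Computes per-timepoint ICCs (fixed-time designs), profile repeatability
#' (fixed-time designs), and the six AUC repeatability variants (ground and
#' increase modes crossed with full-curve, observed-points and
#' windowed-curve bases; curve-based variants require a simulated dataset
#' with stored curves).
#'
#' @param dataset an `observed_dataset` (all components) or a long table
#'   (per-timepoint, profile, and observed-points AUC only).
#' @return A `repeatability_report` list: `per_time` (tibble `time_min`,
#'   `icc`), `profile`, `auc` (tibble `mode`, `basis`, `repeatability`),
#'   `n_individuals`, `n_events`.
#' @export
repeatability_report <- function(dataset) {
  simulated <- inherits(dataset, "observed_dataset")
  obs <- if (simulated) dataset$observed else tibble::as_tibble(dataset)
  check_long_format(obs)
  fixed <- length(unique(lapply(
    split(obs$time_min, interaction(obs$individual_id, obs$event_id,
                                    drop = TRUE)),
    function(t) sort(round(t, 9))))) == 1
  per_time <- NULL
  profile <- NA_real_
  if (fixed) {
    times <- sort(unique(round(obs$time_min, 9)))
    per_time <- tibble::tibble(
      time_min = times,
      icc = vapply(times, function(t) {
        rows <- round(obs$time_min, 9) == t
        icc(obs$value[rows], obs$individual_id[rows])
      }, numeric(1))
    )
    profile <- profile_repeatability(obs)
  }
  bases <- if (simulated) c("full_curve", "observed_points", "windowed_curve")
           else "observed_points"
  grid_rep <- tidyr::expand_grid(mode = c("ground", "increase"), basis = bases)
  grid_rep$repeatability <- mapply(function(m, b) {
    auc_repeatability(if (simulated) dataset else obs, mode = m, basis = b)
  }, grid_rep$mode, grid_rep$basis)
  structure(list(per_time = per_time, profile = profile, auc = grid_rep,
                 n_individuals = length(unique(obs$individual_id)),
                 n_events = length(unique(paste(obs$individual_id,
                                                obs$event_id)))),
            class = "repeatability_report")
}

check_long_format <- function(obs) {
  need <- c("individual_id", "event_id", "time_min", "value")
  miss <- setdiff(need, names(obs))
  if (length(miss) > 0) {
    stop("long-format data must have columns ",
         paste(need, collapse = ", "), " (missing: ",
         paste(miss, collapse = ", "), ")", call. = FALSE)
  }
  invisible(obs)
}

#' @export
print.repeatability_report <- function(x, ...) {
  cat("<repeatability_report> ", x$n_individuals, " individuals, ",
      x$n_events, " events\n", sep = "")
  if (!is.null(x$per_time)) {
    cat("per-timepoint ICC:\n")
    print(as.data.frame(x$per_time), row.names = FALSE)
    cat("profile repeatability:", signif(x$profile, 4), "\n")
  }
  cat("AUC repeatability:\n")
  print(as.data.frame(x$auc), row.names = FALSE)
  invisible(x)
}
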