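# Sensitivity-analysis ensemble: sample parameter sets, run members
# independently, tolerate failures, summarise an uncertainty envelope.

#' Ensemble sampling specification
#'
#' Ranges of the varied parameters. By default members vary the relative
#' degassing rate and an additive shift of the basalt/granite lithology
#' split (+-0.2, clamped into \[0, 1\] when applied). Additional named
#' ranges may target `f_minbiota`, `climate_sensitivity`, `npp_max`,
#' `runoff_half` or `t_eq`.
#'
#' @param n_members Number of members (>= 1).
#' @param degassing_range Interval of relative degassing.
#' @param lithology_shift Interval of the additive basalt-fraction shift.
#' @param extra_ranges Named list of further `c(lo, hi)` intervals.
#' @param rng_seed Integer seed; sampling is deterministic given the seed.
#' @return An object of class `ensemble_spec`.
#' @export
ensemble_spec <- function(n_members, degassing_range = c(0.75, 1.25),
                          lithology_shift = c(-0.2, 0.2),
                          extra_ranges = list(), rng_seed = 1) {
  if (n_members < 1 || n_members != round(n_members))
    stop("`n_members` must be a positive integer", call. = FALSE)
  check_iv <- function(iv, nm) {
    if (length(iv) != 2 || iv[1] > iv[2])
      stop("interval `", nm, "` must be c(lo, hi) with lo <= hi",
           call. = FALSE)
  }
  check_iv(degassing_range, "degassing_range")
  if (degassing_range[1] <= 0)
    stop("degassing must be positive", call. = FALSE)
  check_iv(lithology_shift, "lithology_shift")
  allowed <- c("f_minbiota", "climate_sensitivity", "npp_max",
               "runoff_half", "t_eq")
  for (nm in names(extra_ranges)) {
    if (!nm %in% allowed)
      stop("unsupported extra range `", nm, "`; allowed: ",
           paste(allowed, collapse = ", "), call. = FALSE)
    check_iv(extra_ranges[[nm]], nm)
  }
  structure(list(n_members = as.integer(n_members),
                 degassing_range = degassing_range,
                 lithology_shift = lithology_shift,
                 extra_ranges = extra_ranges, rng_seed = rng_seed),
            class = "ensemble_spec")
}

#' Sample member parameter sets
#'
#' Independent uniform draws from every interval of the specification,
#' deterministic under the specification's seed.
#'
#' @param spec An [ensemble_spec()].
#' @return Data frame with one row per member: `member`, `degassing_rel`,
#'   `lithology_shift` and one column per extra range.
#' @export
sample_params <- function(spec) {
  stopifnot(inherits(spec, "ensemble_spec"))
  withr::with_seed(spec$rng_seed, {
    tab <- data.frame(
      member = seq_len(spec$n_members),
      degassing_rel = stats::runif(spec$n_members,
                                   spec$degassing_range[1],
                                   spec$degassing_range[2]),
      lithology_shift = stats::runif(spec$n_members,
                                     spec$lithology_shift[1],
                                     spec$lithology_shift[2]))
    for (nm in names(spec$extra_ranges)) {
      iv <- spec$extra_ranges[[nm]]
      tab[[nm]] <- stats::runif(spec$n_members, iv[1], iv[2])
    }
    tab
  })
}

apply_member_params <- function(model, world, row) {
  world$basalt_fraction <- ifelse(
    world$land_mask,
    pmin(pmax(world$basalt_fraction + row$lithology_shift, 0), 1),
    NA_real_)
  if (!is.null(row$f_minbiota))
    model$params$weathering$f_minbiota <- row$f_minbiota
  if (!is.null(row$climate_sensitivity))
    model$config$climate_sensitivity <- row$climate_sensitivity
  if (!is.null(row$npp_max))
    model$params$photo$npp_max <- row$npp_max
  if (!is.null(row$runoff_half))
    model$params$photo$runoff_half <- row$runoff_half
  if (!is.null(row$t_eq))
    model$params$climate$t_eq <- row$t_eq
  list(model = model, world = world)
}

#' Run a sensitivity ensemble
#'
#' Runs every member independently to steady state under its sampled
#' parameters; member failures (runaway climates, extinctions) are
#' recorded, never aborting the ensemble. The uncertainty envelope
#' (2.5/50/97.5 percent quantiles of steady relative CO2, temperature,
#' habitable fraction and relative vegetation) is computed over the
#' successful members only.
#'
#' @param spec An [ensemble_spec()].
#' @param world The reference `world_grid`.
#' @param forcing Base [forcing_state()] (the member's degassing replaces
#'   its `degassing_rel`).
#' @param model A calibrated `vc_model` (shared across members, so a
#'   member's parameter shift is a true perturbation of the calibrated
#'   reference).
#' @param param_table Optional pre-sampled (or hand-edited) member table
#'   as returned by [sample_params()]; supply it to replay or to inject
#'   deliberate members.
#' @return An object of class `ensemble_result`: `members` (summary data
#'   frame), `envelope` (quantile matrix per output), `n_success`,
#'   `all_failed` flag and the `param_table` used.
#' @export
run_ensemble <- function(spec, world, forcing, model,
                         param_table = NULL) {
  stopifnot(inherits(spec, "ensemble_spec"), inherits(model, "vc_model"))
  if (is.null(param_table)) param_table <- sample_params(spec)
  n <- nrow(param_table)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    row <- param_table[i, , drop = FALSE]
    mem <- apply_member_params(model, world, row)
    f <- forcing
    f$degassing_rel <- row$degassing_rel
    run <- run_to_steady(carbon_state(1, mem$model$config), f,
                         mem$world, mem$model)
    out[[i]] <- data.frame(
      member = row$member, success = run$success,
      failure_mode = run$failure_mode,
      steady_rco2 = run$steady$rco2, steady_gast = run$steady$gast,
      habitable_fraction = run$steady$habitable_fraction,
      v_rel = run$steady$v_rel, n_steps = run$steady$n_steps)
  }
  members <- cbind(param_table,
                   do.call(rbind, out)[, -1, drop = FALSE])
  ok <- members$success
  probs <- c(0.025, 0.5, 0.975)
  vars <- c("steady_rco2", "steady_gast", "habitable_fraction", "v_rel")
  envelope <- if (any(ok)) {
    sapply(vars, function(v)
      stats::quantile(members[[v]][ok], probs, names = FALSE))
  } else {
    matrix(NA_real_, 3, length(vars), dimnames = list(NULL, vars))
  }
  rownames(envelope) <- paste0("q", probs * 100)
  structure(
    list(members = members, envelope = envelope,
         n_success = sum(ok), all_failed = !any(ok),
         param_table = param_table),
    class = "ensemble_result")
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat(sprintf("<ensemble_result: %d/%d successful members>\n",
              x$n_success, nrow(x$members)))
  if (x$n_success > 0) {
    cat("envelope (2.5/50/97.5%):\n")
    print(round(x$envelope, 4))
  }
  invisible(x)
}
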