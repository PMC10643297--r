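# Subsidy-policy scenario schedules and yearly progressive state updates.

#' Build a subsidy-share schedule for a policy scenario
#'
#' Default trajectories over the `T_years` horizon:
#' \describe{
#'   \item{current}{constant at the measured baseline share (default 0.28,
#'     the 2016/17 growing-season average).}
#'   \item{reduced}{linear ramp from the baseline down to 0.02, giving a
#'     20-year mean of exactly 0.15.}
#'   \item{zero}{the baseline in year 0, then 0 from year 1 onward
#'     (progressive removal; mean ~0).}
#'   \item{universal}{constant at 0.70.}
#' }
#' All trajectories can be overridden by passing `shares` directly.
#'
#' @param name scenario name: `"current"`, `"reduced"`, `"zero"`,
#'   `"universal"`.
#' @param T_years horizon length in years (default 20).
#' @param baseline_share baseline subsidy share (default 0.28).
#' @param shares optional explicit numeric vector of length `T_years`
#'   overriding the default trajectory.
#' @return object of class `scenario_schedule`: list with `name` and `s`
#'   (vector of per-year shares in `[0, 1]`).
#' @export
#' @examples
#' mean(build_schedule("reduced")$s) # 0.15
build_schedule <- function(name = c("current", "reduced", "zero", "universal"),
                           T_years = 20, baseline_share = 0.28, shares = NULL) {
  name <- match.arg(name)
  stopifnot(T_years >= 1)
  s <- if (!is.null(shares)) {
    if (length(shares) != T_years) stop("shares must have length T_years")
    as.numeric(shares)
  } else switch(name,
    current = rep(baseline_share, T_years),
    reduced = if (T_years == 1) baseline_share else
      seq(baseline_share, 0.02, length.out = T_years),
    zero = c(baseline_share, rep(0, T_years - 1)),
    universal = rep(0.70, T_years)
  )
  if (any(s < 0 | s > 1)) stop("subsidy shares must be in [0, 1]")
  structure(list(name = name, s = s), class = "scenario_schedule")
}

#' @export
print.scenario_schedule <- function(x, ...) {
  cat("<scenario_schedule ", x$name, "> T=", length(x$s),
      ", mean share ", round(mean(x$s), 3), "\n", sep = "")
  invisible(x)
}

#' Yearly progressive update of dynamic state variables
#'
#' Advances the variables that change deterministically with time — the
#' household head's age and each cultivated plot's cultivation period —
#' while policy and static variables are held at baseline. Additional
#' update rules (e.g. labour or gender dynamics) can be registered as hooks,
#' each called once per tick with the world and returning it modified. With
#' the progressive switch off, the state is returned untouched.
#'
#' @param world simulation world (list with `households` and `plots`).
#' @param progressive logical switch; `FALSE` disables all updates.
#' @param hooks list of functions `function(world) world` applied in order
#'   after the built-in updates.
#' @return the updated world.
#' @export
progressive_update <- function(world, progressive = TRUE, hooks = list()) {
  if (!progressive) return(world)
  world$households$head_age <- world$households$head_age + 1
  cultivated <- world$plots$fallow_frac < 1
  world$plots$cultivation_period[cultivated] <-
    world$plots$cultivation_period[cultivated] + 1
  for (h in hooks) world <- h(world)
  world
}
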