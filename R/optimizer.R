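#' Genetic-algorithm configuration
#'
#' Settings for the global stage of the registration: a generational GA over
#' six-gene rigid chromosomes, fitness = mutual information under nearest
#' neighbour interpolation with the floating volume downsampled to voxel
#' volume `df` (coarse, fast evaluations). Each generation keeps the top
#' `ceiling(pe * pop)` chromosomes unchanged (elitism), creates
#' `round(pc * pop)` offspring by roulette-selected single-point crossover,
#' and fills the remainder with mutants of roulette-selected chromosomes
#' (`pm = 1 - pe - pc`).
#'
#' @param pop Population size (default 75).
#' @param pe Elite fraction of the total population (default 0.25).
#' @param pc Crossover fraction (default 0.6); mutation takes the rest.
#' @param ranges A [param_ranges()] search envelope.
#' @param df Floating-volume voxel volume for fitness evaluation, mm^3
#'   (default 8).
#' @param bins Histogram bins (default 64).
#' @param stall_generations Stop after this many generations without relative
#'   best-fitness improvement above `stall_tol` (default 10).
#' @param stall_tol Relative improvement threshold (default 1e-4).
#' @param max_generations Hard cap on generations (default 100).
#' @param min_overlap Minimum admissible overlap: chromosomes mapping fewer
#'   than this fraction of the valid floating voxels into the reference field
#'   of view receive the worst fitness (default 0.5). Guards against the
#'   spurious mutual-information maxima that tiny overlaps produce.
#' @return A `ga_config` object.
#' @export
ga_config <- function(pop = 75, pe = 0.25, pc = 0.6, ranges = param_ranges(),
                      df = 8, bins = 64, stall_generations = 10,
                      stall_tol = 1e-4, max_generations = 100,
                      min_overlap = 0.5) {
  pop <- as.integer(pop)
  if (pop < 2L) stop("`pop` must be >= 2", call. = FALSE)
  if (pe < 0 || pc < 0 || pe + pc > 1)
    stop("need pe, pc >= 0 and pe + pc <= 1", call. = FALSE)
  stopifnot(inherits(ranges, "param_ranges"), df > 0, max_generations >= 1)
  structure(list(pop = pop, pe = pe, pc = pc, pm = 1 - pe - pc,
                 ranges = ranges, df = df, bins = bins,
                 stall_generations = as.integer(stall_generations),
                 stall_tol = stall_tol,
                 max_generations = as.integer(max_generations),
                 min_overlap = min_overlap),
            class = "ga_config")
}

#' Downhill-simplex configuration
#'
#' Settings for the local refinement stage: Nelder-Mead maximization of
#' mutual information under partial-volume interpolation with the floating
#' volume at voxel volume `df` (finer than the GA stage). The initial simplex
#' perturbs each parameter of the start point by `init_step` (mm for
#' translations, degrees for rotations).
#'
#' @param df Floating voxel volume, mm^3 (default 3.375, i.e. 1.5 mm edges).
#' @param bins Histogram bins (default 64).
#' @param max_iter Iteration cap per Nelder-Mead pass (default 300).
#' @param restarts Fresh-simplex restarts at the incumbent solution after
#'   each pass (default 1), the standard guard against premature simplex
#'   collapse.
#' @param param_tol Stop when the simplex spans less than this in every
#'   parameter (default 0.05 mm / degrees).
#' @param mi_tol Stop when the simplex MI spread falls below this, bits
#'   (default 1e-5).
#' @param init_step Per-vertex perturbation building the initial simplex
#'   (default 2 mm / 2 degrees).
#' @param min_overlap Minimum admissible overlap fraction, as in
#'   [ga_config()] (default 0.5).
#' @param scheme Histogram estimator for the refinement stage: `"gpve"`
#'   (default) or `"pv"`. Partial-volume weights concentrate whenever the
#'   floating lattice lines up with the reference lattice, carving a
#'   spurious dip into the mutual-information surface exactly at aligned
#'   orientations; the order-2 B-spline kernels of GPVE suppress it, which
#'   is what the refinement stage needs to resolve rotations to sub-degree
#'   accuracy.
#' @param spline_orders Per-axis B-spline orders when `scheme = "gpve"`.
#' @return A `simplex_config` object.
#' @export
simplex_config <- function(df = 3.375, bins = 64, max_iter = 300,
                           param_tol = 0.05, mi_tol = 1e-5, init_step = 2,
                           min_overlap = 0.5, scheme = c("gpve", "pv"),
                           spline_orders = c(2, 2, 2), restarts = 1) {
  scheme <- match.arg(scheme)
  stopifnot(df > 0, param_tol > 0, mi_tol > 0, init_step > 0, max_iter >= 1,
            restarts >= 0)
  structure(list(df = df, bins = bins, max_iter = as.integer(max_iter),
                 param_tol = param_tol, mi_tol = mi_tol, init_step = init_step,
                 min_overlap = min_overlap, scheme = scheme,
                 spline_orders = as.integer(spline_orders),
                 restarts = as.integer(restarts)),
            class = "simplex_config")
}

#' Fitness-proportional (roulette-wheel) selection
#'
#' Draws one index with probability proportional to its fitness score.
#' Scores are shifted by the minimum when any are negative (MI is already
#' nonnegative); if every shifted score is zero the draw is uniform.
#'
#' @param fitness Numeric vector of finite fitness scores.
#' @return A single index in `seq_along(fitness)`.
#' @export
roulette_select <- function(fitness) {
  if (length(fitness) == 0L) stop("empty population", call. = FALSE)
  if (any(!is.finite(fitness))) stop("fitness scores must be finite", call. = FALSE)
  w <- fitness - min(0, min(fitness))
  if (sum(w) <= 0) w <- rep(1, length(fitness))
  sample.int(length(fitness), 1L, prob = w)
}

#' Single-point chromosome crossover
#'
#' Cuts at a uniform position in 1..5 and joins the first `k` genes of
#' `parent_a` with the remaining genes of `parent_b`.
#'
#' @param parent_a,parent_b [rigid_params()] chromosomes.
#' @return Offspring [rigid_params()].
#' @export
ga_crossover <- function(parent_a, parent_b) {
  a <- as_rigid_params(parent_a); b <- as_rigid_params(parent_b)
  k <- sample.int(5L, 1L)
  as_rigid_params(c(unclass(a)[seq_len(k)], unclass(b)[(k + 1):6]))
}

#' Single-gene mutation
#'
#' Replaces one uniformly chosen gene with a uniform draw from its search
#' range.
#'
#' @param chrom A [rigid_params()] chromosome.
#' @param ranges A [param_ranges()].
#' @return Mutated [rigid_params()].
#' @export
ga_mutate <- function(chrom, ranges) {
  stopifnot(inherits(ranges, "param_ranges"))
  p <- unclass(as_rigid_params(chrom))
  g <- sample.int(6L, 1L)
  p[g] <- stats::runif(1, ranges$lower[g], ranges$upper[g])
  as_rigid_params(p)
}

random_chromosome <- function(ranges) {
  as_rigid_params(stats::runif(6, ranges$lower, ranges$upper))
}

#' Global registration stage: genetic algorithm
#'
#' Evolves a population of rigid chromosomes maximizing mutual information
#' (nearest-neighbour histogram, floating volume downsampled to `cfg$df`).
#' Chromosomes with no reference overlap receive fitness 0, the worst
#' admissible MI. Deterministic given the R random seed in effect.
#'
#' @param ref,flt Reference and floating [volume_grid()]s.
#' @param cfg A [ga_config()].
#' @return A `registration_result` with `estimated`, `mi`, and per-generation
#'   `ga_trace` (best and mean fitness).
#' @export
ga_optimize <- function(ref, flt, cfg = ga_config()) {
  stopifnot(inherits(cfg, "ga_config"))
  fltd <- resample_by_df(flt, cfg$df)
  engine <- mi_engine(ref, fltd, scheme = "nn", bins = cfg$bins, na_value = 0,
                      min_overlap = cfg$min_overlap)
  n <- cfg$pop
  n_elite <- min(n, as.integer(ceiling(cfg$pe * n)))
  n_cross <- min(n - n_elite, as.integer(round(cfg$pc * n)))
  n_mut <- n - n_elite - n_cross

  popn <- replicate(n, random_chromosome(cfg$ranges), simplify = FALSE)
  fit <- vapply(popn, engine, numeric(1))
  trace <- data.frame(generation = 0L, best = max(fit), mean = mean(fit))
  best_fit <- max(fit)
  stall <- 0L
  for (gen in seq_len(cfg$max_generations)) {
    ord <- order(fit, decreasing = TRUE)
    elites <- popn[ord[seq_len(n_elite)]]
    offspring <- replicate(n_cross, {
      pa <- popn[[roulette_select(fit)]]
      pb <- popn[[roulette_select(fit)]]
      ga_crossover(pa, pb)
    }, simplify = FALSE)
    mutants <- replicate(n_mut, {
      ga_mutate(popn[[roulette_select(fit)]], cfg$ranges)
    }, simplify = FALSE)
    new_pop <- c(elites, offspring, mutants)
    new_fit <- c(fit[ord[seq_len(n_elite)]],
                 vapply(c(offspring, mutants), engine, numeric(1)))
    popn <- new_pop; fit <- new_fit
    gen_best <- max(fit)
    trace <- rbind(trace, data.frame(generation = gen, best = gen_best,
                                     mean = mean(fit)))
    if (gen_best > best_fit * (1 + cfg$stall_tol)) {
      best_fit <- gen_best
      stall <- 0L
    } else {
      best_fit <- max(best_fit, gen_best)
      stall <- stall + 1L
    }
    if (stall >= cfg$stall_generations) break
  }
  i <- which.max(fit)
  new_registration_result(estimated = popn[[i]], mi = fit[i],
                          ga_trace = tibble::as_tibble(trace),
                          method = "ga")
}

#' Local registration stage: downhill simplex
#'
#' Nelder-Mead maximization of mutual information (partial-volume histogram,
#' floating volume at `cfg$df`) starting from `start`. Standard reflection /
#' expansion / contraction / shrink coefficients (1, 2, 0.5, 0.5); stops at
#' `max_iter` or when the simplex collapses below `param_tol` in every
#' parameter or below `mi_tol` in fitness spread. The returned MI never falls
#' below the start's.
#'
#' @param ref,flt Reference and floating [volume_grid()]s.
#' @param start Starting [rigid_params()].
#' @param cfg A [simplex_config()].
#' @param ranges Optional [param_ranges()] bounding the refinement; `NULL`
#'   leaves it unconstrained.
#' @return A `registration_result` with a per-iteration `simplex_trace`.
#' @export
simplex_refine <- function(ref, flt, start = rigid_params(),
                           cfg = simplex_config(), ranges = NULL) {
  stopifnot(inherits(cfg, "simplex_config"))
  start <- as_rigid_params(start)
  fltd <- resample_by_df(flt, cfg$df)
  engine <- mi_engine(ref, fltd, scheme = cfg$scheme, bins = cfg$bins,
                      spline_orders = cfg$spline_orders, na_value = 0,
                      min_overlap = cfg$min_overlap)
  f <- if (is.null(ranges)) {
    function(x) engine(as_rigid_params(x))
  } else {
    function(x) {
      if (any(x < ranges$lower) || any(x > ranges$upper)) return(0)
      engine(as_rigid_params(x))
    }
  }
  nm <- nm_maximize(f, as.numeric(start), init_step = cfg$init_step,
                    param_tol = cfg$param_tol, f_tol = cfg$mi_tol,
                    max_iter = cfg$max_iter)
  trace <- nm$trace
  for (r in seq_len(cfg$restarts)) {
    nm2 <- nm_maximize(f, nm$par, init_step = cfg$init_step,
                       param_tol = cfg$param_tol, f_tol = cfg$mi_tol,
                       max_iter = cfg$max_iter)
    nm2$trace$iteration <- nm2$trace$iteration + max(trace$iteration)
    trace <- rbind(trace, nm2$trace)
    if (nm2$value > nm$value) nm <- list(par = nm2$par, value = nm2$value)
  }
  new_registration_result(estimated = as_rigid_params(nm$par), mi = nm$value,
                          simplex_trace = tibble::as_tibble(trace),
                          method = "simplex")
}

# Nelder-Mead maximization with explicit initial-simplex control: start plus
# one vertex per parameter perturbed by +init_step. Standard coefficients
# (reflection 1, expansion 2, contraction 0.5, shrink 0.5). The best vertex
# is never discarded, so the returned value is >= f(x0).
nm_maximize <- function(f, x0, init_step, param_tol, f_tol, max_iter) {
  n <- length(x0)
  V <- rbind(x0, t(vapply(seq_len(n), function(j) {
    v <- x0; v[j] <- v[j] + init_step; v
  }, numeric(n))))
  Fv <- apply(V, 1, f)
  trace <- data.frame(iteration = 0L, best = max(Fv))
  for (it in seq_len(max_iter)) {
    ord <- order(Fv, decreasing = TRUE) # maximize: best first
    V <- V[ord, , drop = FALSE]; Fv <- Fv[ord]
    if (max(apply(V, 2, function(col) diff(range(col)))) < param_tol ||
        diff(range(Fv)) < f_tol) break
    centroid <- colMeans(V[seq_len(n), , drop = FALSE])
    worst <- V[n + 1, ]
    xr <- centroid + (centroid - worst)       # reflection
    fr <- f(xr)
    if (fr > Fv[1]) {
      xe <- centroid + 2 * (centroid - worst) # expansion
      fe <- f(xe)
      if (fe > fr) { V[n + 1, ] <- xe; Fv[n + 1] <- fe }
      else { V[n + 1, ] <- xr; Fv[n + 1] <- fr }
    } else if (fr > Fv[n]) {
      V[n + 1, ] <- xr; Fv[n + 1] <- fr
    } else {
      xc <- centroid + 0.5 * ((if (fr > Fv[n + 1]) xr else worst) - centroid)
      fc <- f(xc)
      if (fc > max(fr, Fv[n + 1])) {
        V[n + 1, ] <- xc; Fv[n + 1] <- fc
      } else { # shrink toward the best vertex
        for (i in 2:(n + 1)) {
          V[i, ] <- V[1, ] + 0.5 * (V[i, ] - V[1, ])
          Fv[i] <- f(V[i, ])
        }
      }
    }
    trace <- rbind(trace, data.frame(iteration = it, best = max(Fv)))
  }
  i <- which.max(Fv)
  list(par = unname(V[i, ]), value = unname(Fv[i]), trace = trace)
}

#' Two-stage multiresolution registration
#'
#' The full method: a genetic algorithm explores the whole misalignment
#' envelope on heavily downsampled data with fast nearest-neighbour
#' histograms, then a downhill simplex refines its best chromosome at finer
#' resolution with partial-volume histograms. Fully deterministic under
#' `seed`.
#'
#' @param ref,flt Reference and floating [volume_grid()]s.
#' @param ga_cfg A [ga_config()].
#' @param sx_cfg A [simplex_config()].
#' @param seed Integer seed driving every stochastic step.
#' @return A `registration_result` carrying both stage traces, the final
#'   parameters and MI, and the seed.
#' @examples
#' \donttest{
#' ct <- make_ct_phantom(phantom_spec("ct", dims = c(64, 64, 16)))
#' pet <- make_pet_phantom(phantom_spec("pet", dims = c(64, 64, 16)))
#' fit <- register_volumes(ct, pet, seed = 1)
#' tidy(fit)
#' }
#' @export
register_volumes <- function(ref, flt, ga_cfg = ga_config(),
                             sx_cfg = simplex_config(), seed = 1L) {
  assert_volume(ref); assert_volume(flt)
  res <- with_phantom_seed(seed, {
    ga <- ga_optimize(ref, flt, ga_cfg)
    # the refinement may leave the GA box: the true inverse of a misalignment
    # drawn from the box is only contained in the box's inverse envelope
    sx <- simplex_refine(ref, flt, start = ga$estimated, cfg = sx_cfg,
                         ranges = inverse_envelope(ga_cfg$ranges))
    list(ga = ga, sx = sx)
  })
  new_registration_result(estimated = res$sx$estimated, mi = res$sx$mi,
                          ga_trace = res$ga$ga_trace,
                          simplex_trace = res$sx$simplex_trace,
                          method = "ga+simplex", seed = as.integer(seed),
                          ga_mi = res$ga$mi)
}

new_registration_result <- function(estimated, mi, ga_trace = NULL,
                                    simplex_trace = NULL, method = "ga+simplex",
                                    seed = NA_integer_, ga_mi = NA_real_) {
  structure(list(estimated = estimated, mi = mi, ga_trace = ga_trace,
                 simplex_trace = simplex_trace, method = method, seed = seed,
                 ga_mi = ga_mi),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat("<registration_result> method:", x$method, "\n")
  print(x$estimated)
  cat("  final MI:", format(x$mi, digits = 6), "bits\n")
  if (!is.null(x$ga_trace))
    cat("  GA generations:", max(x$ga_trace$generation), "\n")
  if (!is.null(x$simplex_trace))
    cat("  simplex iterations:", max(x$simplex_trace$iteration), "\n")
  invisible(x)
}

#' Tidy a registration result
#'
#' One row per rigid parameter with its estimate, in broom style.
#'
#' @param x A `registration_result`.
#' @param ... Unused.
#' @return A tibble with columns `parameter`, `estimate`, `unit`.
#' @export
tidy.registration_result <- function(x, ...) {
  tibble::tibble(parameter = param_names,
                 estimate = as.numeric(x$estimated),
                 unit = rep(c("mm", "degrees"), each = 3))
}

#' One-row summary of a registration result
#'
#' @param x A `registration_result`.
#' @param ... Unused.
#' @return A one-row tibble: method, final MI, GA-stage MI, generations,
#'   simplex iterations, seed.
#' @export
glance.registration_result <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    mi = x$mi,
    ga_mi = x$ga_mi,
    ga_generations = if (is.null(x$ga_trace)) NA_integer_ else max(x$ga_trace$generation),
    simplex_iterations = if (is.null(x$simplex_trace)) NA_integer_ else max(x$simplex_trace$iteration),
    seed = x$seed
  )
}

#' Turn an object into a tidy tibble
#'
#' Generic in the style of broom; see [tidy.registration_result()].
#' @param x An object.
#' @param ... Method arguments.
#' @return A tibble.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' One-row model summary
#'
#' Generic in the style of broom; see [glance.registration_result()].
#' @param x An object.
#' @param ... Method arguments.
#' @return A one-row tibble.
#' @export
glance <- function(x, ...) UseMethod("glance")

#' Combined score for ranking optimizer settings
#'
#' For a set of candidate settings with mean transformation errors and mean
#' execution times, each vector is normalized by its maximum and the score is
#' their sum, `s = e_n + t_n`; the setting minimizing the score balances
#' accuracy against cost (used to pick the GA population size). All-zero
#' vectors are normalized by 1.
#'
#' @param errors Nonnegative mean transformation errors, one per setting.
#' @param times Nonnegative mean execution times, one per setting.
#' @return Numeric vector of scores, one per setting.
#' @examples
#' sn_score(errors = c(2, 4), times = c(10, 5))  # both 1.5
#' @export
sn_score <- function(errors, times) {
  if (length(errors) != length(times) || length(errors) < 1L)
    stop("`errors` and `times` must be equal-length, nonempty", call. = FALSE)
  if (any(errors < 0) || any(times < 0))
    stop("entries must be nonnegative", call. = FALSE)
  emax <- max(errors); tmax <- max(times)
  errors / max(emax, if (emax == 0) 1 else emax) +
    times / max(tmax, if (tmax == 0) 1 else tmax)
}
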