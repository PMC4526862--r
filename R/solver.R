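#' Solver parameters for the variational boundary model
#'
#' Bundles the tunable parameters of the variational model and its
#' gradient-flow iteration. Defaults are the published operating point:
#' smoothness weight `alpha = 0.8`, external weight base `beta0 = 0.2`,
#' kernel width `sigma = 0.5` px, time step `dt = 1`, ray half-width
#' `M = 30` px, boundary discretisation `n_points = 540`, ten smoothing
#' passes. The element spacing over alpha (`ds/alpha`) is fixed to one in the
#' iteration, as in the discretised scheme.
#'
#' `sigma_schedule` anneals the kernel width: early stages with a wide kernel
#' extend the capture range of the external force to several pixels (the
#' inter-slice displacement regime), and the final stage runs at `sigma`
#' itself. Pass `sigma_schedule = 0.5` for a single-stage run at the published
#' kernel width.
#'
#' @param alpha Smoothness weight (> 0, dimensionless).
#' @param beta0 External weight base (>= 0); the per-element weight is
#'   `beta_i = beta0 / (1e-6 + max_m g_i(p_m))`, normalising gradient evidence
#'   so inhomogeneous boundary contrast yields comparable pull.
#' @param sigma Final Gaussian kernel width in pixels (> 0).
#' @param sigma_schedule Strictly decreasing vector of kernel widths ending at
#'   `sigma`.
#' @param dt Time step of the gradient flow (> 0).
#' @param M Ray half-width in pixels (integer >= 2).
#' @param n_points Boundary discretisation (integer >= 8).
#' @param smoothing_passes Number of 3-point smoothing passes on ray profiles.
#' @param max_iters Maximum iterations per sigma stage.
#' @param tol Convergence threshold on max |delta r| in pixels.
#' @return A `solver_params` list.
#' @export
solver_params <- function(alpha = 0.8, beta0 = 0.2, sigma = 0.5,
                          sigma_schedule = c(3, 1.5, sigma), dt = 1,
                          M = 30, n_points = 540, smoothing_passes = 10,
                          max_iters = 500, tol = 1e-3) {
  stopifnot(alpha > 0, beta0 >= 0, sigma > 0, dt > 0, M >= 2, n_points >= 8,
            smoothing_passes >= 1, max_iters >= 1, tol > 0)
  if (length(sigma_schedule) < 1 ||
      sigma_schedule[length(sigma_schedule)] != sigma ||
      any(diff(sigma_schedule) >= 0)) {
    stop("`sigma_schedule` must be strictly decreasing and end at `sigma`",
         call. = FALSE)
  }
  structure(list(alpha = alpha, beta0 = beta0, sigma = sigma,
                 sigma_schedule = sigma_schedule, dt = dt,
                 M = as.integer(M), n_points = as.integer(n_points),
                 smoothing_passes = as.integer(smoothing_passes),
                 max_iters = as.integer(max_iters), tol = tol),
            class = "solver_params")
}

# offset positions of the valid-gradient samples: midpoints of the forward
# differences, m + 1/2 for m = -M..M-1
grad_positions <- function(M) seq.int(-M, M - 1L) + 0.5

#' External energy of one ray
#'
#' Kernel-weighted gradient evidence at offset `r`:
#' `E_ext(r) = sum_m g(p_m) * exp(-(p_m - r)^2 / (2 sigma^2))`, with `p_m` the
#' offset midpoints of the valid-gradient samples. Maximising it over `r`
#' moves the element to the (kernel-smoothed) peak of `g` — the strongest
#' intensity drop along its ray.
#'
#' @param g Valid-gradient samples of one ray (length 2M).
#' @param r Scalar offset (or vector of offsets) at which to evaluate.
#' @param sigma Kernel width in pixels.
#' @return Energy value(s), same length as `r`.
#' @export
external_energy <- function(g, r, sigma) {
  p <- grad_positions(length(g) %/% 2L)
  vapply(r, function(ri) sum(g * exp(-(p - ri)^2 / (2 * sigma^2))), numeric(1))
}

#' External force of one ray
#'
#' The derivative of [external_energy()] with respect to the offset:
#' `sum_m g(p_m) * (p_m - r)/sigma^2 * exp(-(p_m - r)^2/(2 sigma^2))`.
#' Positive force pushes the element outward (toward larger offsets).
#'
#' @inheritParams external_energy
#' @return Force value(s), same length as `r`.
#' @export
external_force <- function(g, r, sigma) {
  p <- grad_positions(length(g) %/% 2L)
  vapply(r, function(ri) {
    d <- p - ri
    sum(g * (d / sigma^2) * exp(-d^2 / (2 * sigma^2)))
  }, numeric(1))
}

# Vectorised over all rays: G is N x 2M, r length N. Returns list(force, energy).
ray_force_energy <- function(G, r, sigma, p) {
  D <- matrix(p, nrow = nrow(G), ncol = length(p), byrow = TRUE) - r
  W <- exp(-D^2 / (2 * sigma^2))
  list(force = rowSums(G * D * W) / sigma^2,
       energy = rowSums(G * W))
}

# cyclic tridiagonal system (1 + 2a) r_i - a r_{i+1} - a r_{i-1} = rhs_i,
# solved by a precomputed dense inverse (N is a few hundred; the matrix is
# constant across iterations so the factorisation cost is paid once per dt)
cyclic_smoother <- local({
  cache <- new.env(parent = emptyenv())
  function(n, a) {
    key <- paste(n, signif(a, 15))
    inv <- cache[[key]]
    if (is.null(inv)) {
      A <- diag(1 + 2 * a, n)
      up <- cbind(seq_len(n), c(seq_len(n)[-1], 1L))
      dn <- cbind(seq_len(n), c(n, seq_len(n - 1L)))
      A[up] <- A[up] - a
      A[dn] <- A[dn] - a
      inv <- solve(A)
      cache[[key]] <- inv
    }
    inv
  }
})

# discrete objective: sum_i [ alpha (r_{i+1}-r_i)^2 / 2 - beta_i E_ext_i(r_i) ]
# (ds = 1); `ext` may be precomputed per-ray external energies
discrete_energy <- function(r, beta, ext, alpha, use_smoothness = TRUE) {
  e <- -sum(beta * ext)
  if (use_smoothness) {
    dr <- c(r[-1], r[1]) - r
    e <- e + alpha * sum(dr^2) / 2
  }
  e
}

#' Evolve boundary offsets by the discretised gradient flow
#'
#' Minimises the discrete variational objective
#' `sum_i [ alpha (r_{i+1} - r_i)^2 / 2 - beta_i E_ext(g_i, r_i, sigma) ]`
#' over per-element scalar offsets, starting from all-zero offsets. Each
#' iteration takes a forward (explicit) step on the external force and a
#' backward (semi-implicit) step on the cyclic smoothness term — the
#' cyclic-tridiagonal solve that makes the smoothing unconditionally stable
#' at `dt = 1` — then clips offsets to `[-M+1, M-1]` so the force never needs
#' g outside its sampled range. If a step would increase the discrete
#' objective, the time step is halved for that iteration (backtracking), so
#' the objective is non-increasing at every fixed sigma.
#'
#' Kernel widths run through `params$sigma_schedule`, each stage warm-starting
#' the next, which extends the capture range of the narrow final kernel.
#'
#' @param rays A conditioned `ray_field` (see [condition_rays()]).
#' @param params A [solver_params()].
#' @param init_offsets Optional initial offsets (default all zero, as in the
#'   published procedure).
#' @param use_smoothness If `FALSE`, drop the smoothness term: each ray then
#'   independently climbs its own external energy (used for oracle checks).
#' @param keep_energy If `TRUE`, record the objective after every iteration.
#' @return An `offset_solution`: list with `offsets`, `iterations`,
#'   `converged`, `residual_history`, `stages` (per-sigma tibble) and
#'   optionally `energy_history` (list of per-stage energy traces).
#' @export
evolve_offsets <- function(rays, params, init_offsets = NULL,
                           use_smoothness = TRUE, keep_energy = FALSE) {
  stopifnot(inherits(rays, "ray_field"), inherits(params, "solver_params"))
  G <- rays$grad
  if (is.null(G)) stop("ray field is not conditioned; call condition_rays()", call. = FALSE)
  n <- nrow(G)
  M <- rays$M
  p <- grad_positions(M)
  beta <- params$beta0 / (1e-6 + apply(G, 1, max))
  r <- if (is.null(init_offsets)) numeric(n) else {
    stopifnot(length(init_offsets) == n)
    as.numeric(init_offsets)
  }
  lim <- M - 1
  gain <- params$dt * beta / params$alpha

  residuals <- numeric(0)
  stages <- vector("list", length(params$sigma_schedule))
  energy_hist <- list()
  total_iters <- 0L
  converged <- FALSE

  for (si in seq_along(params$sigma_schedule)) {
    sigma <- params$sigma_schedule[si]
    fe <- ray_force_energy(G, r, sigma, p)
    if (!all(is.finite(fe$force))) {
      stop("non-finite external force at element ",
           which(!is.finite(fe$force))[1], call. = FALSE)
    }
    e_cur <- discrete_energy(r, beta, fe$energy, params$alpha, use_smoothness)
    stage_iters <- 0L
    stage_conv <- FALSE
    e_trace <- e_cur
    for (k in seq_len(params$max_iters)) {
      dt_try <- params$dt
      repeat {
        rhs <- r + dt_try * (beta / params$alpha) * fe$force
        r_new <- if (use_smoothness) {
          drop(cyclic_smoother(n, dt_try) %*% rhs)
        } else rhs
        r_new <- pmin(pmax(r_new, -lim), lim)
        fe_new <- ray_force_energy(G, r_new, sigma, p)
        e_new <- discrete_energy(r_new, beta, fe_new$energy, params$alpha,
                                 use_smoothness)
        if (e_new <= e_cur || dt_try < 1e-10) break
        dt_try <- dt_try / 2
      }
      if (e_new > e_cur) {        # fully stalled: keep the current iterate
        r_new <- r
        fe_new <- fe
        e_new <- e_cur
      }
      res <- max(abs(r_new - r))
      r <- r_new
      fe <- fe_new
      e_cur <- e_new
      residuals <- c(residuals, res)
      if (keep_energy) e_trace <- c(e_trace, e_cur)
      stage_iters <- stage_iters + 1L
      if (res < params$tol) { stage_conv <- TRUE; break }
    }
    total_iters <- total_iters + stage_iters
    stages[[si]] <- tibble::tibble(sigma = sigma, iterations = stage_iters,
                                   converged = stage_conv)
    if (keep_energy) energy_hist[[si]] <- e_trace
    converged <- stage_conv
  }
  if (!converged) {
    warning("offset evolution did not converge at the final sigma stage",
            call. = FALSE)
  }
  out <- structure(list(
    offsets = r,
    iterations = total_iters,
    converged = converged,
    residual_history = residuals,
    stages = dplyr::bind_rows(stages),
    beta = beta
  ), class = "offset_solution")
  if (keep_energy) out$energy_history <- energy_hist
  out
}

#' @export
print.offset_solution <- function(x, ...) {
  cat(sprintf("<offset_solution> %d elements, %d iterations, %sconverged\n",
              length(x$offsets), x$iterations, if (x$converged) "" else "NOT "))
  invisible(x)
}

#' Apply converged offsets to a boundary
#'
#' Moves every boundary element to `origin_i + r_i * n_i`, the final position
#' along its ray, and re-canonicalises the result to CCW order. If the moved
#' polygon self-intersects it is repaired by one light arc-length resampling;
#' a polygon that still self-intersects afterwards raises an error.
#'
#' @param boundary The [closed_boundary()] the rays originated from.
#' @param normals The exterior normals used for the rays.
#' @param solution An `offset_solution` (or bare numeric vector of offsets).
#' @return The refined `closed_boundary`.
#' @export
boundary_from_offsets <- function(boundary, normals, solution) {
  b <- as_boundary(boundary, check = FALSE)
  r <- if (inherits(solution, "offset_solution")) solution$offsets else solution
  stopifnot(length(r) == nrow(b), nrow(normals) == nrow(b))
  x <- b$x + r * normals[, 1]
  y <- b$y + r * normals[, 2]
  if (!is_simple_polygon(x, y)) {
    warning("refined boundary self-intersects; applying resampling repair",
            call. = FALSE)
    rep_b <- resample_closed_polyline(
      closed_boundary(tibble::tibble(x = x, y = y), check = FALSE), nrow(b))
    if (!is_simple_polygon(rep_b$x, rep_b$y)) {
      stop("refined boundary self-intersects even after repair", call. = FALSE)
    }
    return(rep_b)
  }
  closed_boundary(tibble::tibble(x = x, y = y), check = FALSE)
}
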