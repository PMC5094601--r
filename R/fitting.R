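#' Force and convergence parameters for skeleton fitting
#'
#' Houses the three force constants, the region radii that gate which cloud
#' points act on which sphere, the HSV gate selecting red (face-colored)
#' points, and the integration/convergence controls of the physics-style
#' simulation. Region radii are proportional to sphere radii: the attraction
#' region of sphere i is `A_i = regionA_factor * radius_i`, the exclusive
#' claim region `B_i = regionB_factor * radius_i`, the repulsion gate
#' `C_i = regionC_factor * radius_i`. The head color region `A_3` has an
#' absolute radius. None of these constants are measured quantities; the
#' defaults were calibrated once on synthetic pose-recovery experiments (see
#' the methods vignette) and are all overridable.
#'
#' @param alpha Attraction constant (per metre of point offset).
#' @param beta Repulsion constant (per active point, unit direction).
#' @param gamma Face-color attraction constant acting on the jaw sphere.
#' @param regionA_factor,regionB_factor,regionC_factor Region radii as
#'   multiples of each sphere's radius; `regionB_factor < regionA_factor`.
#' @param regionA3_radius Radius (m) of the ball about the head sphere within
#'   which red points attract the jaw.
#' @param hsv_gate List with `h_min`, `h_max`, `s_min`, `v_min`; hue wraps,
#'   so `h_min > h_max` selects the red interval through 1.0/0.0.
#' @param step_size Overdamped integration step (displacement = step_size *
#'   force / mass).
#' @param max_step Trust-region cap on any sphere's displacement per
#'   iteration (m); keeps the update stable for arbitrarily dense clouds.
#' @param convergence_eps Steady state: maximum per-sphere shift (m) below
#'   which the simulation stops.
#' @param max_iters Iteration cap; non-convergence is reported, not hidden.
#' @param constraint_sweeps Gauss-Seidel sweeps in the constraint projection.
#' @param repulsion_sign `-1` (default) pushes spheres away from gated
#'   surface points, confining the model inside the hull; `+1` uses the
#'   opposite (attractive) sign.
#' @param refine_factor Coarse-to-fine annealing of the attraction region in
#'   [fit_frame()]: after the simulation reaches a steady state at
#'   `regionA_factor`, it is re-run once with the attraction region shrunk
#'   by this factor, which tightens the equilibrium onto the local surface
#'   while the wide first phase provides capture range for frame-to-frame
#'   motion. `1` disables the refinement phase.
#' @return A `skf_params` list.
#' @export
fit_params <- function(alpha = 0.2, beta = 0.002, gamma = 2,
                       regionA_factor = 3, regionB_factor = 1.4,
                       regionC_factor = 1.5, regionA3_radius = 0.10,
                       hsv_gate = list(h_min = 0.95, h_max = 0.05,
                                       s_min = 0.4, v_min = 0.2),
                       step_size = 1, max_step = 0.02,
                       convergence_eps = 0.001, max_iters = 200L,
                       constraint_sweeps = 10L, repulsion_sign = -1,
                       refine_factor = 0.7) {
  stopifnot(alpha >= 0, beta >= 0, gamma >= 0,
            regionB_factor < regionA_factor, regionA3_radius > 0,
            step_size > 0, max_step > 0, convergence_eps > 0, max_iters >= 1,
            repulsion_sign %in% c(-1, 1),
            refine_factor > 0, refine_factor <= 1,
            regionB_factor < refine_factor * regionA_factor)
  structure(
    list(alpha = alpha, beta = beta, gamma = gamma,
         regionA_factor = regionA_factor, regionB_factor = regionB_factor,
         regionC_factor = regionC_factor, regionA3_radius = regionA3_radius,
         hsv_gate = hsv_gate, step_size = step_size, max_step = max_step,
         convergence_eps = convergence_eps, max_iters = as.integer(max_iters),
         constraint_sweeps = as.integer(constraint_sweeps),
         repulsion_sign = repulsion_sign, refine_factor = refine_factor),
    class = "skf_params"
  )
}

cloud_positions <- function(cloud) cbind(cloud$x, cloud$y, cloud$z)

forces_tibble <- function(model, F) {
  tibble::tibble(sphere = model$spheres$id, label = model$spheres$label,
                 fx = F[, 1], fy = F[, 2], fz = F[, 3])
}

#' Attraction forces from cloud points to model spheres
#'
#' Each sphere i is pulled toward the cloud points inside its region `A_i`
#' that are not claimed by any other sphere's exclusion ball `B_k`:
#' `fa_i = alpha * m_i * sum_j a_j * (P_j - S_i)`.
#'
#' @param cloud World-frame cloud tibble.
#' @param model A `skf_model`.
#' @param pose Current pose tibble.
#' @param params A [fit_params()].
#' @return List with `forces` (tibble: sphere, label, fx, fy, fz) and
#'   `active` (per-sphere integer vectors of contributing point rows).
#' @export
attraction_forces <- function(cloud, model, pose, params = fit_params()) {
  S <- pose_matrix(pose)
  if (!nrow(cloud)) {
    return(list(forces = forces_tibble(model, matrix(0, 23, 3)),
                active = rep(list(integer()), 23)))
  }
  res <- cpp_attraction(cloud_positions(cloud), S, model$spheres$radius,
                        model$spheres$mass, params$alpha,
                        params$regionA_factor, params$regionB_factor)
  list(forces = forces_tibble(model, res$force), active = res$active)
}

#' Repulsion forces confining the model inside the hull
#'
#' A point j acts on sphere i when it lies inside the gate region `C_i` and
#' its outward (camera-oriented) normal sees the sphere center on the
#' interior side, `N_j . (P_j - S_i) > 0`. Each active point contributes
#' `beta * m_i` along the unit direction from the point to the sphere center
#' (sign configurable, see [fit_params()]). Gated points with undefined
#' normals are skipped with a warning.
#'
#' @inheritParams attraction_forces
#' @return As [attraction_forces()].
#' @export
repulsion_forces <- function(cloud, model, pose, params = fit_params()) {
  S <- pose_matrix(pose)
  if (!nrow(cloud)) {
    return(list(forces = forces_tibble(model, matrix(0, 23, 3)),
                active = rep(list(integer()), 23)))
  }
  N <- cbind(cloud$nx, cloud$ny, cloud$nz)
  res <- cpp_repulsion(cloud_positions(cloud), N, S, model$spheres$radius,
                       model$spheres$mass, params$beta, params$regionC_factor,
                       params$repulsion_sign)
  if (res$n_skipped > 0) {
    warn(sprintf("%d gated points had undefined normals and were skipped",
                 res$n_skipped))
  }
  list(forces = forces_tibble(model, res$force), active = res$active)
}

hsv_gate_mask <- function(cloud, gate) {
  h <- cloud$h; s <- cloud$s; v <- cloud$v
  hin <- if (gate$h_min <= gate$h_max) {
    h >= gate$h_min & h <= gate$h_max
  } else {
    h >= gate$h_min | h <= gate$h_max   # wrapped red interval
  }
  ok <- hin & s >= gate$s_min & v >= gate$v_min
  ok & !is.na(ok)
}

#' Face-color attraction on the jaw sphere
#'
#' Red points (HSV gate) within the ball `A_3` around the head sphere pull
#' the jaw sphere: `fah = gamma * m_1 * sum_j f_j * (P_j - S_1)`. This pins
#' the head direction to the red face patch.
#'
#' @inheritParams attraction_forces
#' @return List with `force` (length-3 vector on sphere 1) and `active`
#'   (row indices of contributing points).
#' @export
jaw_color_force <- function(cloud, model, pose, params = fit_params()) {
  S <- pose_matrix(pose)
  if (!nrow(cloud)) return(list(force = c(0, 0, 0), active = integer()))
  d2 <- (cloud$x - S[3, 1])^2 + (cloud$y - S[3, 2])^2 + (cloud$z - S[3, 3])^2
  sel <- which(hsv_gate_mask(cloud, params$hsv_gate) &
                 d2 <= params$regionA3_radius^2)
  m1 <- model$spheres$mass[model$spheres$id == 1]
  if (!length(sel)) return(list(force = c(0, 0, 0), active = integer()))
  f <- params$gamma * m1 * c(
    sum(cloud$x[sel] - S[1, 1]),
    sum(cloud$y[sel] - S[1, 2]),
    sum(cloud$z[sel] - S[1, 3])
  )
  list(force = f, active = sel)
}

total_forces <- function(cloud, model, pose, params) {
  fa <- attraction_forces(cloud, model, pose, params)
  fr <- repulsion_forces(cloud, model, pose, params)
  fh <- jaw_color_force(cloud, model, pose, params)
  F <- as.matrix(fa$forces[, c("fx", "fy", "fz")]) +
    as.matrix(fr$forces[, c("fx", "fy", "fz")])
  F[1, ] <- F[1, ] + fh$force
  n_active <- lengths(fa$active) + lengths(fr$active)
  n_active[1] <- n_active[1] + length(fh$active)
  list(F = F, n_active = n_active)
}

#' One overdamped dynamics step under given forces
#'
#' Displaces each sphere by `step_size * force / mass` (capped at
#' `max_step`), then projects the result back onto the skeleton constraints:
#' bone lengths are restored exactly and bend angles clamped into their
#' limits. With zero forces a valid pose is a fixed point.
#'
#' @param pose Current pose tibble.
#' @param forces 23 x 3 numeric matrix (rows in sphere-id order), or the
#'   `forces` tibble returned by the force functions.
#' @param model A `skf_model`.
#' @param params A [fit_params()].
#' @return The new pose tibble.
#' @export
step_dynamics <- function(pose, forces, model, params = fit_params()) {
  if (is.data.frame(forces)) {
    forces <- as.matrix(forces[order(forces$sphere), c("fx", "fy", "fz")])
  }
  if (any(!is.finite(forces))) abort("forces contain non-finite values")
  S <- pose_matrix(pose)
  disp <- params$step_size * forces / model$spheres$mass
  mag <- sqrt(rowSums(disp^2))
  over <- mag > params$max_step
  if (any(over)) {
    disp[over, ] <- disp[over, , drop = FALSE] * (params$max_step / mag[over])
  }
  project_pose(model, matrix_to_pose(model, S + disp,
                                     pose$time_s[[1]] %||% NA_real_),
               sweeps = params$constraint_sweeps)
}

#' Fit the skeleton model into one frame's point cloud
#'
#' Iterates force evaluation and constrained overdamped dynamics until the
#' simulated system reaches a steady state in which every sphere's
#' per-iteration shift falls below `convergence_eps`, or `max_iters` is hit.
#' An empty cloud exerts no forces, so the initial pose is returned converged.
#'
#' @inheritParams attraction_forces
#' @param init Initial pose tibble (for video, the previous frame's fit).
#' @return A `skf_fit` object: list with `pose`, `iterations`, `converged`,
#'   `final_max_shift` (m).
#' @export
fit_frame <- function(cloud, model, init, params = fit_params()) {
  run_phase <- function(pose, phase_params) {
    iters <- 0L
    shift <- 0
    converged <- TRUE
    repeat {
      if (iters >= phase_params$max_iters) {
        converged <- FALSE
        break
      }
      tf <- total_forces(cloud, model, pose, phase_params)
      # precondition by the active point count: the raw force sums grow with
      # the local point density, so the fixed-point iteration is only a
      # contraction after per-sphere normalization (the equilibrium, where
      # the summed forces vanish, is unchanged)
      F <- tf$F / pmax(1, tf$n_active)
      new_pose <- step_dynamics(pose, F, model, phase_params)
      shift <- max(sqrt(rowSums((pose_matrix(new_pose) -
                                   pose_matrix(pose))^2)))
      pose <- new_pose
      iters <- iters + 1L
      if (shift < phase_params$convergence_eps) break
    }
    list(pose = pose, iters = iters, converged = converged, shift = shift)
  }

  p1 <- run_phase(init, params)
  iters <- p1$iters
  res <- p1
  if (params$refine_factor < 1) {
    fine <- params
    fine$regionA_factor <- params$refine_factor * params$regionA_factor
    res <- run_phase(p1$pose, fine)
    iters <- iters + res$iters
  }
  structure(
    list(pose = res$pose, iterations = iters,
         converged = p1$converged && res$converged,
         final_max_shift = res$shift),
    class = "skf_fit"
  )
}

#' @export
print.skf_fit <- function(x, ...) {
  cat(sprintf("<skf_fit> %s after %d iterations (final max shift %.2f mm)\n",
              if (x$converged) "converged" else "NOT converged",
              x$iterations, 1000 * x$final_max_shift))
  invisible(x)
}
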