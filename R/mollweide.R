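#' Solve the Mollweide auxiliary angle
#'
#' The Mollweide projection maps latitude \eqn{\phi} through an auxiliary
#' angle \eqn{\theta} satisfying \eqn{2\theta + \sin 2\theta = \pi \sin\phi}.
#' The equation is solved by Newton-Raphson started at \eqn{\theta_0 = \phi},
#' falling back to bisection on \eqn{[-\pi/2, \pi/2]} for any element that has
#' not converged after 50 iterations. The poles, where the Newton derivative
#' vanishes, are returned analytically as \eqn{\pm\pi/2}.
#'
#' @param phi latitude(s) in radians, \eqn{|\phi| \le \pi/2}.
#' @param tol convergence tolerance on \eqn{|2\theta + \sin 2\theta - \pi\sin\phi|}.
#' @return theta in radians, same length as `phi`.
#' @export
mollweide_theta <- function(phi, tol = 1e-10) {
  if (tol <= 0) stop_("tol must be positive")
  if (any(abs(phi) > pi / 2 + 1e-12)) stop_("latitude outside [-pi/2, pi/2]")
  phi <- pmin(pi / 2, pmax(-pi / 2, phi))
  target <- pi * sin(phi)
  theta <- phi
  pole <- abs(abs(phi) - pi / 2) < 1e-14
  theta[pole] <- sign(phi[pole]) * pi / 2
  active <- which(!pole)

  # Newton iterations. Near the poles the derivative 2 + 2cos(2theta)
  # vanishes and convergence degrades from quadratic to linear, so the
  # stopping rule is on the step size (theta accuracy), not just on the
  # residual; anything still moving after 100 iterations goes to bisection.
  step_tol <- min(tol, 1e-12)
  for (iter in seq_len(100)) {
    if (!length(active)) break
    fa <- 2 * theta[active] + sin(2 * theta[active]) - target[active]
    deriv <- 2 + 2 * cos(2 * theta[active])
    step <- fa / pmax(deriv, 1e-12)
    new_theta <- pmin(pi / 2, pmax(-pi / 2, theta[active] - step))
    moved <- abs(new_theta - theta[active])
    theta[active] <- new_theta
    done <- moved < step_tol & abs(fa) < tol
    active <- active[!done]
  }

  # Bisection fallback (monotone increasing objective), run to theta
  # interval below 1e-13.
  if (length(active)) {
    lo <- rep(-pi / 2, length(active))
    hi <- rep(pi / 2, length(active))
    for (iter in seq_len(60)) {
      mid <- (lo + hi) / 2
      fm <- 2 * mid + sin(2 * mid) - target[active]
      neg <- fm < 0
      lo[neg] <- mid[neg]
      hi[!neg] <- mid[!neg]
    }
    theta[active] <- (lo + hi) / 2
  }
  theta
}

#' Mollweide planar coordinates
#'
#' Closed-form Mollweide projection
#' \eqn{x = (2\sqrt2/\pi)\,\lambda\cos\theta}, \eqn{y = \sqrt2 \sin\theta}.
#' For a full sphere (\eqn{\lambda \in [-\pi, \pi]}) the image is a 2:1
#' ellipse; for one hemisphere chart (\eqn{\lambda \in [-\pi/2, \pi/2]}) it
#' lies inside the square \eqn{[-\sqrt2, \sqrt2]^2}.
#'
#' @param phi,lambda latitude and longitude in radians.
#' @param tol tolerance passed to [mollweide_theta()].
#' @return data frame with columns `theta`, `x`, `y`.
#' @export
mollweide_xy <- function(phi, lambda, tol = 1e-10) {
  theta <- mollweide_theta(phi, tol)
  data.frame(theta = theta,
             x = (2 * sqrt(2) / pi) * lambda * cos(theta),
             y = sqrt(2) * sin(theta))
}

#' Project one hemisphere of a source space
#'
#' Applies the Mollweide projection to every vertex of the requested
#' hemisphere. Vertices must lie on the half-sphere chart
#' (\eqn{|\lambda| \le \pi/2}); anything off-chart is an error.
#'
#' @param space a `cortical_space`.
#' @param hemisphere `"left"` or `"right"`.
#' @param tol tolerance for the auxiliary-angle solve.
#' @return data frame: `vertex_id`, `phi`, `lambda`, `theta`, `x`, `y`.
#' @export
project_hemisphere <- function(space, hemisphere = c("left", "right"),
                               tol = 1e-10) {
  stopifnot(inherits(space, "cortical_space"))
  hemisphere <- match.arg(hemisphere)
  v <- space$vertices[space$vertices$hemisphere == hemisphere, ]
  if (any(abs(v$lambda) > pi / 2 + 1e-12)) {
    stop_("vertex longitude outside the hemisphere chart [-pi/2, pi/2]")
  }
  xy <- mollweide_xy(v$phi, v$lambda, tol)
  data.frame(vertex_id = v$vertex_id, phi = v$phi, lambda = v$lambda,
             theta = xy$theta, x = xy$x, y = xy$y)
}
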