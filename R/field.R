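# Electrostatic forward model for the needle-pair geometry: analytic
# two-cylinder field map, lethal-threshold ablation area, and a nonlinear
# finite-difference Laplace solver used as a numerical oracle.
#
# All maps are 2D cross-sections at the electrode midline (per unit
# length along the needles); reported resistances are scaled by an
# effective depth (the exposure length for needles).

#' Analytic field map of a needle pair
#'
#' Potential of two parallel cylinders at +/- V/2 in a uniform medium via
#' the exact image-line-charge construction: line charges at
#' `x = +/- b`, `b = sqrt((D/2)^2 - a^2)`, giving
#' `phi(P) = V/2 * ln(r-/r+) / acosh(D/(2a))`. The electrode circles are
#' exact equipotentials of this field. The field magnitude `E = |grad phi|`
#' is evaluated by central differences on a uniform Cartesian grid.
#'
#' @param geom A [needle_pair_geometry()].
#' @param applied_V Electrode potential difference, volts.
#' @param grid_spacing Grid spacing in meters (default 50 um); must
#'   resolve the electrode radius with at least 5 cells.
#' @param domain Side length of the square domain in meters (default 4 cm),
#'   centered between the electrodes.
#' @return An object of class `field_map`: list with `x`, `y` (cell-center
#'   coordinates, m), `phi` (V), `E` (V/cm), `mask` (logical, electrode
#'   interiors), `spacing` (m), `depth` (m, exposure), and
#'   `method = "analytic"`.
#' @export
bipolar_field_map <- function(geom, applied_V, grid_spacing = 50e-6,
                              domain = 0.04) {
  stopifnot(inherits(geom, "geometry_spec"))
  if (geom$kind != "needle_pair")
    stop("analytic field map defined for needle-pair geometries",
         call. = FALSE)
  a <- geom$radius / 1000
  D <- geom$spacing / 100
  if (a / grid_spacing < 5)
    stop("grid too coarse: need >= 5 cells across the electrode radius (",
         "spacing <= ", signif(a / 5, 3), " m)", call. = FALSE)
  b <- sqrt((D / 2)^2 - a^2)
  k <- (applied_V / 2) / acosh(D / (2 * a))
  x <- seq(-domain / 2, domain / 2, by = grid_spacing)
  y <- seq(-domain / 2, domain / 2, by = grid_spacing)
  xm <- matrix(x, nrow = length(x), ncol = length(y))
  ym <- matrix(y, nrow = length(x), ncol = length(y), byrow = TRUE)
  rp <- sqrt((xm - b)^2 + ym^2)   # to + line charge
  rm <- sqrt((xm + b)^2 + ym^2)   # to - line charge
  phi <- k * log(rm / rp)
  mask <- ((xm - D / 2)^2 + ym^2 <= a^2) | ((xm + D / 2)^2 + ym^2 <= a^2)
  phi[(xm - D / 2)^2 + ym^2 <= a^2] <- applied_V / 2
  phi[(xm + D / 2)^2 + ym^2 <= a^2] <- -applied_V / 2
  E <- .grad_mag(phi, grid_spacing) / 100  # V/m -> V/cm
  structure(list(x = x, y = y, phi = phi, E = E, mask = mask,
                 spacing = grid_spacing, depth = geom$exposure / 100,
                 applied_V = applied_V, method = "analytic"),
            class = "field_map")
}

# |grad phi| by central differences (one-sided at borders), V per meter.
.grad_mag <- function(phi, h) {
  nx <- nrow(phi); ny <- ncol(phi)
  gx <- phi; gy <- phi
  gx[2:(nx - 1), ] <- (phi[3:nx, ] - phi[1:(nx - 2), ]) / (2 * h)
  gx[1, ] <- (phi[2, ] - phi[1, ]) / h
  gx[nx, ] <- (phi[nx, ] - phi[nx - 1, ]) / h
  gy[, 2:(ny - 1)] <- (phi[, 3:ny] - phi[, 1:(ny - 2)]) / (2 * h)
  gy[, 1] <- (phi[, 2] - phi[, 1]) / h
  gy[, ny] <- (phi[, ny] - phi[, ny - 1]) / h
  sqrt(gx^2 + gy^2)
}

#' @export
print.field_map <- function(x, ...) {
  cat(sprintf(
    "<field_map [%s]: %d x %d cells @ %g um, V = %g V, max E = %.3g V/cm>\n",
    x$method, length(x$x), length(x$y), x$spacing * 1e6, x$applied_V,
    max(x$E[!x$mask])))
  invisible(x)
}

#' Ablation area above a lethal field threshold
#'
#' Cells die where the local field reaches the lethal electric field
#' threshold (EFT); the predicted ablation cross-section is the area of
#' grid cells with `E >= EFT`, excluding electrode interiors. Monotone
#' non-increasing in the threshold.
#'
#' @param fmap A `field_map` (analytic or finite-difference).
#' @param lethal_EFT Lethal threshold, V/cm (> 0).
#' @return An object of class `ablation_estimate`: list with `area_cm2`,
#'   `lethal_EFT`, and `method`.
#' @export
ablation_area <- function(fmap, lethal_EFT) {
  stopifnot(inherits(fmap, "field_map"))
  if (lethal_EFT <= 0) stop("'lethal_EFT' must be positive (V/cm)",
                            call. = FALSE)
  n <- sum(fmap$E >= lethal_EFT & !fmap$mask)
  structure(list(area_cm2 = n * fmap$spacing^2 * 1e4,
                 lethal_EFT = lethal_EFT, method = fmap$method),
            class = "ablation_estimate")
}

#' @export
print.ablation_estimate <- function(x, ...) {
  cat(sprintf("<ablation area: %.3g cm^2 at EFT %g V/cm [%s]>\n",
              x$area_cm2, x$lethal_EFT, x$method))
  invisible(x)
}

#' Nonlinear finite-difference Laplace solver
#'
#' Solves `div(sigma(E) grad phi) = 0` on a uniform 2D grid with Dirichlet
#' electrodes and insulating (Neumann) outer boundaries, by Picard
#' iteration: solve the linear problem at frozen conductivity, recompute
#' `E = |grad phi|`, relax the conductivity update, repeat until the
#' potential changes by less than `tol` (relative max-norm). Face
#' conductivities are arithmetic means of adjacent cells; the linear
#' systems are solved sparsely (5-point stencil). Tissue resistance is
#' computed from the total current crossing the positive-electrode
#' boundary, scaled by the geometry's effective depth (needle exposure
#' length; for plates, area / width, so the plate limit reproduces
#' `R = l / (sigma A)`).
#'
#' @param geom A `geometry_spec` (needle pair or plate).
#' @param applied_V Electrode potential difference, volts.
#' @param sigma_fn Function `sigma(E_Vpercm)` returning conductivity in
#'   S/m; must be positive and bounded. Use `function(E) sigma0` for a
#'   uniform medium (converges in one Picard step).
#' @param grid_spacing Grid spacing, m (default 50 um).
#' @param domain Square domain side for needle pairs, m (default 4 cm).
#' @param tol Relative tolerance on the potential (default 1e-6).
#' @param max_iter Maximum Picard iterations (default 500).
#' @param relax Under-relaxation factor on the conductivity update
#'   (default 0.5; steeply field-dependent conductivities can limit-cycle
#'   under lighter damping).
#' @return A `field_map` (method `"fd"`) with additional elements
#'   `R` (ohm, total), `R_per_length` (ohm m), `iterations`, `residual`.
#' @export
fd_laplace <- function(geom, applied_V, sigma_fn, grid_spacing = 50e-6,
                       domain = 0.04, tol = 1e-6, max_iter = 500L,
                       relax = 0.5) {
  stopifnot(inherits(geom, "geometry_spec"), is.function(sigma_fn))
  if (geom$kind == "needle_pair") {
    a <- geom$radius / 1000
    D <- geom$spacing / 100
    x <- seq(-domain / 2, domain / 2, by = grid_spacing)
    y <- seq(-domain / 2, domain / 2, by = grid_spacing)
    xm <- matrix(x, length(x), length(y))
    ym <- matrix(y, length(x), length(y), byrow = TRUE)
    # dilate the rasterized electrode by half a cell so the staircase
    # boundary straddles the true circle instead of inscribing it
    a_eff <- a + grid_spacing / 2
    pos_mask <- (xm - D / 2)^2 + ym^2 <= a_eff^2
    neg_mask <- (xm + D / 2)^2 + ym^2 <= a_eff^2
    if (sum(pos_mask) < 5L)
      stop("grid too coarse to resolve the electrode", call. = FALSE)
    depth <- geom$exposure / 100
  } else {
    l <- geom$thickness / 1000
    wdt <- geom$diameter / 1000
    x <- seq(0, l, by = grid_spacing)
    y <- seq(0, wdt, by = grid_spacing)
    xm <- matrix(x, length(x), length(y))
    ym <- matrix(y, length(x), length(y), byrow = TRUE)
    pos_mask <- xm <= grid_spacing / 2          # x = 0 face
    neg_mask <- xm >= l - grid_spacing / 2      # x = l face
    depth <- plate_area(wdt) / wdt
  }
  nx <- length(x); ny <- length(y); h <- grid_spacing
  dir_mask <- pos_mask | neg_mask
  phi_d <- matrix(0, nx, ny)
  phi_d[pos_mask] <- applied_V / 2
  phi_d[neg_mask] <- -applied_V / 2

  free <- which(!dir_mask)            # column-major linear indices
  idx_of <- matrix(0L, nx, ny)
  idx_of[free] <- seq_along(free)

  phi <- phi_d
  sig <- matrix(sigma_fn(0), nx, ny)
  residual <- Inf; it <- 0L
  repeat {
    it <- it + 1L
    sol <- .fd_solve_linear(sig, phi_d, dir_mask, free, idx_of, nx, ny, h)
    dphi <- max(abs(sol - phi)) / max(abs(phi_d))
    phi <- sol
    E_vpcm <- .grad_mag(phi, h) / 100
    sig_new <- matrix(sigma_fn(as.vector(E_vpcm)), nx, ny)
    if (any(!is.finite(sig_new)) || any(sig_new <= 0))
      stop("sigma_fn must return positive finite conductivities",
           call. = FALSE)
    sig <- relax * sig_new + (1 - relax) * sig
    residual <- dphi
    if (residual < tol || it >= max_iter) break
  }
  if (residual >= tol)
    stop(sprintf(
      "Picard iteration did not converge in %d iterations (residual %.3g)",
      max_iter, residual), call. = FALSE)

  I2d <- .electrode_current(phi, sig, pos_mask, nx, ny)
  R_per_length <- applied_V / I2d
  structure(list(x = x, y = y, phi = phi, E = .grad_mag(phi, h) / 100,
                 mask = dir_mask & !(geom$kind == "plate"), spacing = h,
                 depth = depth, applied_V = applied_V, method = "fd",
                 R = R_per_length / depth, R_per_length = R_per_length,
                 iterations = it, residual = residual),
            class = "field_map")
}

# One linear solve of the 5-point variable-coefficient Laplacian with
# Dirichlet electrode nodes and Neumann outer boundary (mirror ghosts:
# boundary-crossing faces simply carry zero flux and are omitted).
.fd_solve_linear <- function(sig, phi_d, dir_mask, free, idx_of, nx, ny, h) {
  nfree <- length(free)
  fi <- ((free - 1L) %% nx) + 1L       # row (x index)
  fj <- ((free - 1L) %/% nx) + 1L      # col (y index)

  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  diag_acc <- numeric(nfree)
  rhs <- numeric(nfree)

  for (d in 1:4) {
    di <- c(1L, -1L, 0L, 0L)[d]
    dj <- c(0L, 0L, 1L, -1L)[d]
    ni <- fi + di; nj <- fj + dj
    inside <- ni >= 1L & ni <= nx & nj >= 1L & nj <= ny
    w <- which(inside)
    nb_lin <- (nj[w] - 1L) * nx + ni[w]
    # arithmetic-mean face conductivity
    sface <- (sig[free[w]] + sig[nb_lin]) / 2
    diag_acc[w] <- diag_acc[w] + sface
    nb_free <- idx_of[nb_lin]
    isf <- nb_free > 0L
    ii <- c(ii, w[isf]); jj <- c(jj, nb_free[isf])
    xx <- c(xx, -sface[isf])
    rhs[w[!isf]] <- rhs[w[!isf]] + sface[!isf] * phi_d[nb_lin[!isf]]
  }
  A <- Matrix::sparseMatrix(i = c(seq_len(nfree), ii),
                            j = c(seq_len(nfree), jj),
                            x = c(diag_acc, xx), dims = c(nfree, nfree))
  # the operator is symmetric positive definite: sparse Cholesky
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(A), LDL = FALSE, perm = TRUE)
  sol_free <- as.numeric(Matrix::solve(ch, rhs, system = "A"))
  out <- phi_d
  out[free] <- sol_free
  out
}

# Total current (per unit depth) leaving the positive electrode: sum of
# face fluxes sigma_face * (phi_e - phi_neighbor) over electrode-to-tissue
# faces (face length h cancels the gradient's 1/h). Node-centered grid:
# faces whose transverse coordinate sits on the domain edge carry half a
# cell of boundary length (trapezoid weight 1/2), which makes the uniform
# plate limit exact.
.electrode_current <- function(phi, sig, pos_mask, nx, ny) {
  pos <- which(pos_mask)
  pi_ <- ((pos - 1L) %% nx) + 1L
  pj <- ((pos - 1L) %/% nx) + 1L
  I <- 0
  for (d in 1:4) {
    di <- c(1L, -1L, 0L, 0L)[d]
    dj <- c(0L, 0L, 1L, -1L)[d]
    ni <- pi_ + di; nj <- pj + dj
    inside <- ni >= 1L & ni <= nx & nj >= 1L & nj <= ny
    w <- which(inside)
    nb <- (nj[w] - 1L) * nx + ni[w]
    ext <- !pos_mask[nb]
    we <- w[ext]
    sface <- (sig[pos[we]] + sig[nb[ext]]) / 2
    tw <- if (di != 0L) {  # x-flux: transverse coordinate is y
      ifelse(pj[we] == 1L | pj[we] == ny, 0.5, 1)
    } else {               # y-flux: transverse coordinate is x
      ifelse(pi_[we] == 1L | pi_[we] == nx, 0.5, 1)
    }
    I <- I + sum(tw * sface * (phi[pos[we]] - phi[nb[ext]]))
  }
  I
}
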