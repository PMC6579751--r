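# Thomas algorithm for tridiagonal systems: a (sub), b (diag), d (super).
tridiag_solve <- function(a, b, d, rhs) {
  n <- length(b)
  cp <- numeric(n); dp <- numeric(n)
  cp[1] <- d[1] / b[1]
  dp[1] <- rhs[1] / b[1]
  for (i in 2:n) {
    m <- b[i] - a[i] * cp[i - 1]
    cp[i] <- if (i < n) d[i] / m else 0
    dp[i] <- (rhs[i] - a[i] * dp[i - 1]) / m
  }
  x <- numeric(n)
  x[n] <- dp[n]
  for (i in (n - 1):1) x[i] <- dp[i] - cp[i] * x[i + 1]
  x
}

# Bernoulli function of the Scharfetter-Gummel scheme, numerically safe.
bernoulli_fn <- function(u) {
  out <- numeric(length(u))
  small <- abs(u) < 1e-10
  out[small] <- 1 - u[small] / 2
  big <- !small
  out[big] <- u[big] / (exp(u[big]) - 1)
  # avoid overflow for strongly negative u: u/(e^u - 1) -> -u e^{-u} ~ -u
  neg <- u < -500
  out[neg] <- -u[neg]
  out
}

#' Solve the 1D Poisson--Nernst--Planck system at one voltage
#'
#' Steady-state, area-averaged electrodiffusion: the reduced Poisson
#' equation d/dz(eps eps0 A dphi/dz) = -(F sum_i z_i c_i) A - e rho_f is
#' coupled to flux-divergence-free Nernst--Planck transport
#' J_i = -D_i f_D A (dc_i/dz + z_i F/(R T) c_i dphi/dz). Discretization uses
#' exponential-fitted Scharfetter--Gummel fluxes; the nonlinear coupling is
#' resolved by Gummel (alternating) iteration with a Boltzmann-linearized
#' Poisson step, which keeps concentrations positive without ad hoc damping.
#' Boundary conditions: phi = V at the left (intracellular) end, 0 at the
#' right; concentrations pinned to the baths.
#'
#' @param sys a [pnp_system()].
#' @param V applied membrane voltage phi_left - phi_right, mV.
#' @param tol convergence threshold on max |delta phi| per Gummel cycle,
#'   volts (default 1e-6).
#' @param max_iter iteration cap (error, with residual history, if hit).
#' @param init optional warm start (a previous `pnp_solution`); used
#'   internally for fixed-charge continuation.
#' @return object of class `pnp_solution`: `phi` (mV), `conc` (mM matrix,
#'   node x species), `flux` (mol/s per species, +z positive), `current`
#'   (pA; inward, i.e. extracellular-to-intracellular, is negative),
#'   `flux_constancy` (max relative spatial deviation), `iterations`,
#'   `converged`.
#' @export
solve_pnp <- function(sys, V, tol = 1e-6, max_iter = 10000, init = NULL) {
  # strong fixed charge: ramp it up in stages, warm-starting each stage
  # (continuation), which keeps the Gummel iteration in its basin
  qtot <- sum(abs(sys$rho_f)) * (sys$z[2] - sys$z[1])
  if (is.null(init) && qtot > 2) {
    sol <- NULL
    for (f in c(0.25, 0.5, 0.75, 1)) {
      sys_f <- sys
      sys_f$rho_f <- f * sys$rho_f
      sol <- solve_pnp(sys_f, V, tol = if (f < 1) 1e-4 else tol,
                       max_iter = max_iter,
                       init = if (is.null(sol)) NA else sol)
      sol$init <- NULL
    }
    return(sol)
  }
  sp <- sys$species
  n <- length(sys$z)
  hz <- (sys$z[2] - sys$z[1]) * 1e-10            # m
  A <- sys$area * 1e-20                          # m^2
  Amid <- (A[-1] + A[-n]) / 2
  epsmid <- (sys$eps[-1] + sys$eps[-n]) / 2 * .EPS0
  Tk <- sys$temperature
  Vt <- .RGAS * Tk / .FARADAY                    # thermal voltage, V
  rho_line <- sys$rho_f * .ECHARGE / 1e-10       # C/m
  Dm <- sp$D * 1e-4 * sp$f_D                     # m^2/s in-pore
  ns <- nrow(sp)
  V_volt <- V / 1000

  if (is.list(init)) {
    phi <- init$phi / 1000
    conc <- init$conc
  } else {
    phi <- V_volt * (1 - (seq_len(n) - 1) / (n - 1))
    conc <- sapply(seq_len(ns), function(i) {
      sp$c_left[i] + (sp$c_right[i] - sp$c_left[i]) *
        (seq_len(n) - 1) / (n - 1)
    })
    if (is.null(dim(conc))) conc <- matrix(conc, nrow = n)
  }

  # Scharfetter-Gummel flux between nodes j and j+1, with
  # u = z (phi_{j+1} - phi_j) / Vt:  J = g [B(u) c_j - B(-u) c_{j+1}]
  # (drift limit J = -g c u: cations flow down the potential gradient)
  np_solve <- function(i) {
    u <- sp$valence[i] * diff(phi) / Vt
    Bp <- bernoulli_fn(u); Bm <- bernoulli_fn(-u)
    g <- Dm[i] * Amid / hz
    a <- numeric(n); b <- numeric(n); d <- numeric(n); rhs <- numeric(n)
    b[1] <- 1; rhs[1] <- sp$c_left[i]
    b[n] <- 1; rhs[n] <- sp$c_right[i]
    for (j in 2:(n - 1)) {
      a[j] <- -g[j - 1] * Bp[j - 1]
      b[j] <- g[j] * Bp[j] + g[j - 1] * Bm[j - 1]
      d[j] <- -g[j] * Bm[j]
    }
    tridiag_solve(a, b, d, rhs)
  }

  history <- numeric(0)
  converged <- FALSE
  expc <- function(x) exp(pmin(pmax(x, -60), 60))
  for (it in seq_len(max_iter)) {
    # nonlinear Poisson step in Slotboom form: concentrations follow the
    # potential as c_i = S_i exp(-z_i phi / Vt) with S_i frozen from the
    # last transport solve; the inner damped Newton handles arbitrarily
    # stiff fixed charge where a linearized step oscillates
    phi_new <- phi
    for (newton in 1:60) {
      cb <- sapply(seq_len(ns), function(i) {
        conc[, i] * expc(-sp$valence[i] * (phi_new - phi) / Vt)
      })
      qv <- .FARADAY * as.vector(cb %*% sp$valence) * A
      dq <- .FARADAY / Vt * as.vector(cb %*% (sp$valence^2)) * A
      a <- numeric(n); b <- numeric(n); d <- numeric(n); rhs <- numeric(n)
      b[1] <- 1; rhs[1] <- 0
      b[n] <- 1; rhs[n] <- 0
      for (j in 2:(n - 1)) {
        a[j] <- epsmid[j - 1] * Amid[j - 1] / hz^2
        d[j] <- epsmid[j] * Amid[j] / hz^2
        b[j] <- -(a[j] + d[j]) - dq[j]
        # residual of Poisson at current phi_new
        rhs[j] <- -(a[j] * phi_new[j - 1] - (a[j] + d[j]) * phi_new[j] +
                      d[j] * phi_new[j + 1] + qv[j] + rho_line[j])
      }
      # fixed boundary values
      phi_new[1] <- V_volt; phi_new[n] <- 0
      dphi_newton <- tridiag_solve(a, b, d, rhs)
      dphi_newton <- pmin(pmax(dphi_newton, -2 * Vt), 2 * Vt)
      phi_new <- phi_new + dphi_newton
      phi_new[1] <- V_volt; phi_new[n] <- 0
      if (max(abs(dphi_newton)) < 1e-9) break
    }
    dphi <- max(abs(phi_new - phi))
    history <- c(history, dphi)
    phi <- phi_new
    for (i in seq_len(ns)) conc[, i] <- pmax(np_solve(i), 1e-15)
    if (dphi < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    stop("PNP solver did not converge in ", max_iter,
         " iterations; last residuals: ",
         paste(signif(utils::tail(history, 5), 3), collapse = ", "),
         call. = FALSE)
  }
  # fluxes at interfaces (mol/s), species-wise
  flux <- numeric(ns)
  fc <- 0
  for (i in seq_len(ns)) {
    u <- sp$valence[i] * diff(phi) / Vt
    g <- Dm[i] * Amid / hz
    Jif <- g * (bernoulli_fn(u) * conc[-n, i] -
                  bernoulli_fn(-u) * conc[-1, i])
    flux[i] <- mean(Jif)
    if (abs(flux[i]) > 0) {
      fc <- max(fc, max(abs(Jif - flux[i])) / abs(flux[i]))
    }
  }
  current <- sum(.FARADAY * sp$valence * flux) * 1e12   # pA, +z positive
  structure(list(phi = phi * 1000, conc = conc, flux = flux,
                 current = current, flux_constancy = fc,
                 iterations = it, converged = converged,
                 z = sys$z, species = sp$name, V = V),
            class = "pnp_solution")
}

#' @export
print.pnp_solution <- function(x, ...) {
  cat("<pnp_solution> V =", x$V, "mV  I =", signif(x$current, 4),
      "pA  (", x$iterations, "iterations, flux constancy",
      signif(x$flux_constancy, 2), ")\n")
  invisible(x)
}

#' Current--voltage curve, reversal potential and rectification
#'
#' Solves the system across a voltage ramp; the reversal potential is
#' refined by bisection between the bracketing samples to 0.1 mV. The
#' rectification index is |I(-100 mV)| / |I(+100 mV)| (> 1 means inward
#' rectification).
#'
#' @param sys a [pnp_system()].
#' @param voltages mV (default -100..100 by 10).
#' @return object of class `iv_curve`: tibble of `voltage`/`current` with
#'   attributes `v_rev` (mV or NA if no crossing) and `rectification`.
#' @export
iv_curve <- function(sys, voltages = seq(-100, 100, by = 10)) {
  voltages <- sort(voltages)
  cur <- vapply(voltages, function(v) solve_pnp(sys, v)$current, 0)
  v_rev <- NA_real_
  s <- sign(cur)
  cross <- which(s[-1] * s[-length(s)] <= 0 & (s[-1] != 0 | s[-length(s)] != 0))
  if (length(cross) > 0) {
    lo <- voltages[cross[1]]; hi <- voltages[cross[1] + 1]
    flo <- cur[cross[1]]
    while (hi - lo > 0.1) {
      mid <- (lo + hi) / 2
      fm <- solve_pnp(sys, mid)$current
      if (sign(fm) == sign(flo) && fm != 0) {
        lo <- mid; flo <- fm
      } else {
        hi <- mid
      }
    }
    v_rev <- (lo + hi) / 2
  }
  i_neg <- cur[which.min(abs(voltages - (-100)))]
  i_pos <- cur[which.min(abs(voltages - 100))]
  rect <- abs(i_neg) / abs(i_pos)
  out <- tibble(voltage = voltages, current = cur)
  class(out) <- c("iv_curve", class(out))
  attr(out, "v_rev") <- v_rev
  attr(out, "rectification") <- rect
  out
}

#' @rdname iv_curve
#' @param object an `iv_curve`.
#' @param ... unused.
#' @method autoplot iv_curve
#' @export
autoplot.iv_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$voltage,
                                       y = .data$current)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "voltage (mV)", y = "current (pA)") +
    ggplot2::theme_minimal()
}

#' @method glance iv_curve
#' @export
glance.iv_curve <- function(x, ...) {
  tibble(v_rev = attr(x, "v_rev"),
         rectification = attr(x, "rectification"),
         i_min = min(x$current), i_max = max(x$current))
}

#' Goldman--Hodgkin--Katz current (analytic reference)
#'
#' Constant-field flux through a uniform neutral pore; used as an
#' independent check on the PNP solver in the appropriate limit, and for
#' quick permeability estimates.
#'
#' @param species_table species table; permeability per species is
#'   `D * f_D / length`.
#' @param V applied voltage (left minus right), mV.
#' @param length pore length, Angstrom.
#' @param area pore cross-section, Angstrom^2.
#' @param temperature Kelvin.
#' @return total current in pA (+z positive, matching [solve_pnp()]).
#' @export
ghk_current <- function(species_table, V, length, area,
                        temperature = 298.15) {
  sp <- species_table
  if (any(sp$c_left == 0 & sp$c_right == 0)) {
    stop("species with zero concentration on both sides is undefined",
         call. = FALSE)
  }
  Vt <- .RGAS * temperature / .FARADAY
  v <- V / 1000
  L <- length * 1e-10
  A <- area * 1e-20
  P <- sp$D * 1e-4 * sp$f_D / L
  u <- sp$valence * v / Vt
  flux <- ifelse(
    abs(u) < 1e-10,
    P * (sp$c_left - sp$c_right) +
      P * u * (sp$c_left + sp$c_right) / 2,
    P * u * (sp$c_left - sp$c_right * exp(-u)) / (1 - exp(-u))
  )
  sum(.FARADAY * sp$valence * flux * A) * 1e12
}

#' Nernst equilibrium potential
#'
#' @param valence charge number.
#' @param c_left,c_right concentrations (mM), left = intracellular.
#' @param temperature Kelvin.
#' @return potential phi_left - phi_right at zero flux, mV:
#'   `(RT/zF) ln(c_right/c_left)`.
#' @export
nernst <- function(valence, c_left, c_right, temperature = 298.15) {
  stopifnot(c_left > 0, c_right > 0)
  1000 * .RGAS * temperature / (valence * .FARADAY) * log(c_right / c_left)
}
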