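#' Q10 temperature factor
#'
#' Multiplicative temperature scaling `Q10^((T - T_ref)/10)`: rates
#' increase `Q10`-fold for every 10 degC of warming above the reference
#' temperature. Equals 1 at `T = T_ref` and is strictly increasing in `T`
#' for `Q10 > 1`.
#'
#' @param T_c Temperature (degC); vectorised.
#' @param Q10 Temperature coefficient, must be positive.
#' @param T_ref Reference temperature (degC), default 10.
#' @return Numeric vector of dimensionless factors.
#' @examples
#' temperature_factor(20, 2.95) # one decade above reference: 2.95
#' temperature_factor(0, 2)     # 2^(-1) = 0.5
#' @export
temperature_factor <- function(T_c, Q10, T_ref = 10) {
  if (!is.numeric(Q10) || any(Q10 <= 0))
    stop("Q10 must be positive", call. = FALSE)
  Q10^((T_c - T_ref) / 10)
}

# Cubic sigmoid substrate limitation x^3/(x^3 + h^3): the single source
# of truth shared by uptake, diagnostics and the Taylor attribution.
monod_cubic <- function(x, h) x^3 / (x^3 + h^3)

#' Partition bulk bacterial biomass between substrate pools
#'
#' Total bacterial carbon biomass is split linearly between a free-living
#' (DOC-feeding) and a particle-attached (POC-feeding) fraction according
#' to the dissolved share of the total organic substrate,
#' `phi_DOC = DOC / (DOC + POC)`. The partition closes exactly:
#' `B_DOC + B_POC == B`.
#'
#' When both substrate pools are zero the dissolved fraction is undefined;
#' by convention `phi_DOC = 0` (all biomass nominally attached) and a
#' warning is raised.
#'
#' @param B Total bacterial carbon biomass (mmol C m^-3); vectorised.
#' @param DOC,POC Substrate concentrations (mmol C m^-3); vectorised.
#' @return An object of class `bact_state`: list with `B`, `B_DOC`,
#'   `B_POC`, `phi_DOC` (equal-length numeric vectors).
#' @examples
#' partition_biomass(10, DOC = 100, POC = 100) # even split
#' partition_biomass(7, DOC = 5, POC = 0)      # all free-living
#' @export
partition_biomass <- function(B, DOC, POC) {
  n <- max(length(B), length(DOC), length(POC))
  B <- rep_len(as.numeric(B), n)
  DOC <- rep_len(as.numeric(DOC), n)
  POC <- rep_len(as.numeric(POC), n)
  if (any(B < 0) || any(DOC < 0) || any(POC < 0))
    stop("B, DOC and POC must be non-negative", call. = FALSE)
  tot <- DOC + POC
  degenerate <- tot == 0
  if (any(degenerate))
    warning("DOC + POC = 0 in ", sum(degenerate),
            " cell(s); phi_DOC set to 0 by convention", call. = FALSE)
  phi <- ifelse(degenerate, 0, DOC / tot)
  B_DOC <- B * phi
  structure(list(B = B, B_DOC = B_DOC, B_POC = B - B_DOC, phi_DOC = phi),
            class = "bact_state")
}

#' DOC uptake rate of free-living bacteria
#'
#' Monod-type limitation with a cubic sigmoid (fast response near
#' saturation, steep shutdown under strong limitation) scaled by the Q10
#' temperature factor:
#' `BCD_DOC = mu_max * f_T * DOC^3/(DOC^3 + X_DOC^3) * B_DOC`.
#'
#' @param state `bact_state` from [partition_biomass()].
#' @param f `bact_forcing` from [env_forcing()].
#' @param p `bact_params`.
#' @return DOC uptake rate (mmol C m^-3 d^-1), vectorised.
#' @export
uptake_doc <- function(state, f, p) {
  f_T <- temperature_factor(f$T_c, p$Q10_B, p$T_ref)
  f_DOC <- monod_cubic(f$DOC, p$X_DOC)
  p$mu_max * f_T * f_DOC * state$B_DOC
}

#' POC uptake rate of particle-attached bacteria
#'
#' Contois-type limitation (half-saturation scales with the attached
#' biomass itself, reflecting colony growth on particles), a cubic
#' sigmoid, and a Martin-curve-like depth attenuation:
#' `BCD_POC = mu_max * min(1, (z/z0)^b) * POC^3/(POC^3 + (X_POC*B_POC)^3)
#' * B_POC`. The depth factor is clamped at 1 above the reference depth
#' `z0` (including `z = 0`).
#'
#' @inheritParams uptake_doc
#' @return POC uptake rate (mmol C m^-3 d^-1), vectorised.
#' @export
uptake_poc <- function(state, f, p) {
  f_depth <- pmin(1, ifelse(f$z <= 0, 1, (f$z / p$z0)^p$b_exp))
  f_POC <- ifelse(f$POC == 0, 0,
                  monod_cubic(f$POC, p$X_POC * state$B_POC))
  p$mu_max * f_depth * f_POC * state$B_POC
}

#' Bacterial respiration
#'
#' Basal (temperature-scaled, biomass-proportional) plus activity
#' respiration, with an extra cost tied to the oxygen regulating factor
#' `f_O = DO^3/(DO^3 + h_o^3)`:
#' \describe{
#'   \item{`low_oxygen_extra` (default)}{`R = b_B*f_T*B +
#'     (gamma_a + gamma_o*(1 - f_O)) * BCD` — the additional respiration
#'     appears under low oxygen, matching the stated biology of reduced
#'     metabolic efficiency in anaerobic conditions.}
#'   \item{`as_printed`}{`R = b_B*f_T*B + (gamma_a + gamma_o*f_O) * BCD`,
#'     the literal published formula.}
#' }
#'
#' @inheritParams uptake_doc
#' @param BCD Total carbon demand (mmol C m^-3 d^-1), vectorised.
#' @return List with `R` (mmol C m^-3 d^-1) and `f_O` (dimensionless).
#' @export
respiration <- function(state, f, p, BCD) {
  if (any(BCD < 0)) stop("BCD must be non-negative", call. = FALSE)
  f_T <- temperature_factor(f$T_c, p$Q10_B, p$T_ref)
  f_O <- monod_cubic(f$DO, p$h_o)
  oxy <- if (p$oxygen_mode == "low_oxygen_extra") 1 - f_O else f_O
  list(R = p$b_B * f_T * state$B + (p$gamma_a + p$gamma_o * oxy) * BCD,
       f_O = f_O)
}

#' Microzooplankton grazing on bacteria
#'
#' Holling Type 2 grazing with prey-specific capture efficiencies
#' `e = X/(X + mu_Z)` and potential food `F_c = sum(delta*e*X)` over
#' bacteria and phytoplankton. The bacterial loss is
#' `G = r_Z0 * f_T_Z * delta_ZB*e_ZB*B / (F_c + h_ZF) * Z`
#' (the bacterial share of total ingestion times the saturating total
#' uptake), bounded above by `r_Z0 * f_T_Z * Z`.
#'
#' @inheritParams uptake_doc
#' @return List with `G` (mmol C m^-3 d^-1), `F_c`, `e_ZB`, `e_ZP`,
#'   `f_T_Z`.
#' @export
grazing <- function(state, f, p) {
  f_T_Z <- temperature_factor(f$T_c, p$Q10_Z, p$T_ref)
  e_ZB <- state$B / (state$B + p$mu_Z)
  e_ZP <- f$P / (f$P + p$mu_Z)
  e_ZB[state$B == 0 & p$mu_Z == 0] <- 0
  e_ZP[f$P == 0 & p$mu_Z == 0] <- 0
  F_c <- p$delta_ZB * e_ZB * state$B + p$delta_ZP * e_ZP * f$P
  G <- p$r_Z0 * f_T_Z * p$delta_ZB * e_ZB * state$B / (F_c + p$h_ZF) * f$Z
  list(G = G, F_c = F_c, e_ZB = e_ZB, e_ZP = e_ZP, f_T_Z = f_T_Z)
}

#' Temperature-dependent bacterial mortality
#'
#' Non-grazing loss (viral lysis and senescence are not resolved
#' separately): `M = d_B * f_T * B`.
#'
#' @inheritParams uptake_doc
#' @return Mortality loss (mmol C m^-3 d^-1), vectorised.
#' @export
mortality <- function(state, f, p) {
  p$d_B * temperature_factor(f$T_c, p$Q10_B, p$T_ref) * state$B
}

#' Full rate diagnostics of the bacterial box model
#'
#' Composes uptake, respiration, grazing and mortality into the biomass
#' tendency `dB/dt = BP - G - M` with `BP = BCD - R`, and reports every
#' intermediate factor. Production is split between free-living and
#' attached groups proportionally to their share of carbon demand
#' (`BP_DOC = BGE * BCD_DOC`). `BGE = BP/BCD` is `NA` where `BCD = 0`.
#'
#' @inheritParams uptake_doc
#' @return A `data.frame` (class `bact_rates`) with columns `BCD`,
#'   `BCD_DOC`, `BCD_POC`, `R`, `BP`, `BP_DOC`, `BP_POC`, `G`, `M`,
#'   `dBdt`, `BGE`, `f_T_B`, `f_T_Z`, `f_DOC`, `f_POC`, `f_depth`, `f_O`,
#'   `F_c`, `e_ZB`, `e_ZP`; one row per cell.
#' @examples
#' p <- bact_params()
#' st <- partition_biomass(1, DOC = 10, POC = 2)
#' f <- env_forcing(T_c = 10, DOC = 10, POC = 2, Z = 0.5, P = 1, z = 10)
#' bact_rates(st, f, p)[, c("BCD", "BP", "BGE", "dBdt")]
#' @export
bact_rates <- function(state, f, p) {
  BCD_DOC <- uptake_doc(state, f, p)
  BCD_POC <- uptake_poc(state, f, p)
  BCD <- BCD_DOC + BCD_POC
  resp <- respiration(state, f, p, BCD)
  gr <- grazing(state, f, p)
  M <- mortality(state, f, p)
  BP <- BCD - resp$R
  BGE <- ifelse(BCD > 0, BP / BCD, NA_real_)
  share <- ifelse(BCD > 0, BP / BCD, 0)
  f_T_B <- temperature_factor(f$T_c, p$Q10_B, p$T_ref)
  out <- data.frame(
    BCD = BCD, BCD_DOC = BCD_DOC, BCD_POC = BCD_POC,
    R = resp$R, BP = BP,
    BP_DOC = share * BCD_DOC, BP_POC = share * BCD_POC,
    G = gr$G, M = M, dBdt = BP - gr$G - M, BGE = BGE,
    f_T_B = f_T_B, f_T_Z = gr$f_T_Z,
    f_DOC = monod_cubic(f$DOC, p$X_DOC),
    f_POC = ifelse(f$POC == 0, 0,
                   monod_cubic(f$POC, p$X_POC * state$B_POC)),
    f_depth = pmin(1, ifelse(f$z <= 0, 1, (f$z / p$z0)^p$b_exp)),
    f_O = resp$f_O, F_c = gr$F_c, e_ZB = gr$e_ZB, e_ZP = gr$e_ZP
  )
  class(out) <- c("bact_rates", "data.frame")
  out
}

#' Time integration of the bacterial box model
#'
#' Explicit (forward Euler) stepping of bulk biomass `B`, re-partitioned
#' against the current DOC/POC each step. Forcing does not feed back on
#' substrate pools (one-way coupling, as when diagnosing archived Earth
#' system model output). Negative excursions are clipped at zero and
#' counted.
#'
#' Two modes:
#' \describe{
#'   \item{`transient`}{steps through a time-indexed forcing series (one
#'     entry of `forcing` per step; scalar forcing is recycled) for
#'     `n_steps` steps, returning the trajectory.}
#'   \item{`to_steady`}{iterates under fixed forcing until
#'     `|dB/dt| < tol_rel * max(B, B_floor)` in every cell or `max_steps`
#'     is reached. Vectorised over cells: `B0` and `forcing` may describe
#'     many independent columns at once.}
#' }
#'
#' @param B0 Initial bulk biomass (mmol C m^-3); vector = independent
#'   cells (`to_steady`) .
#' @param forcing `bact_forcing`; for `transient`, element i of each
#'   field is the forcing of step i.
#' @param p `bact_params`.
#' @param dt Time step (d).
#' @param mode `"transient"` or `"to_steady"`.
#' @param n_steps Number of steps in transient mode (default: forcing
#'   length).
#' @param tol_rel,B_floor,max_steps Steady-state controls.
#' @return List with `B` (final biomass vector), `state`, `rates` (final
#'   [bact_rates()] row(s)), `converged` (logical vector, `to_steady`),
#'   `steps`, `clipped` (count of negativity clips), and — in transient
#'   mode or scalar steady mode — `trajectory`, a data.frame of `step`,
#'   `time`, `B` and all rate diagnostics.
#' @examples
#' p <- bact_params()
#' f <- env_forcing(T_c = 15, DOC = 20, POC = 5, Z = 0.5, P = 1, z = 10)
#' out <- bact_integrate(0.5, f, p, mode = "to_steady")
#' out$converged
#' @export
bact_integrate <- function(B0, forcing, p, dt = 0.1,
                           mode = c("to_steady", "transient"),
                           n_steps = NULL,
                           tol_rel = 1e-6, B_floor = 1e-8,
                           max_steps = 1e5) {
  mode <- match.arg(mode)
  stopifnot(dt > 0, all(B0 >= 0))
  nf <- length(forcing$T_c)
  if (nf < 1) stop("forcing series is empty", call. = FALSE)
  pick <- function(i) {
    j <- if (nf == 1) 1 else i
    structure(lapply(forcing, `[`, j), class = "bact_forcing")
  }
  clipped <- 0L

  if (mode == "transient") {
    if (is.null(n_steps)) n_steps <- nf
    if (length(B0) != 1) stop("transient mode is single-cell", call. = FALSE)
    B <- B0
    traj <- vector("list", n_steps)
    for (i in seq_len(n_steps)) {
      fi <- pick(i)
      st <- partition_biomass(B, fi$DOC, fi$POC)
      r <- bact_rates(st, fi, p)
      traj[[i]] <- cbind(step = i, time = i * dt, B = B, r)
      B <- B + dt * r$dBdt
      if (B < 0) { B <- 0; clipped <- clipped + 1L }
    }
    traj <- do.call(rbind, traj)
    fl <- pick(n_steps)
    st <- partition_biomass(B, fl$DOC, fl$POC)
    return(list(B = B, state = st, rates = bact_rates(st, fl, p),
                trajectory = traj, steps = n_steps, clipped = clipped))
  }

  # to_steady: fixed forcing, vectorised over cells
  n <- max(length(B0), nf)
  B <- rep_len(as.numeric(B0), n)
  f <- structure(lapply(forcing, rep_len, n), class = "bact_forcing")
  active <- rep(TRUE, n)
  steps <- 0L
  r <- NULL
  while (steps < max_steps) {
    st <- partition_biomass(B, f$DOC, f$POC)
    r <- bact_rates(st, f, p)
    conv <- abs(r$dBdt) < tol_rel * pmax(B, B_floor)
    active <- !conv
    if (!any(active)) break
    Bn <- B + dt * r$dBdt * active
    neg <- Bn < 0
    if (any(neg)) { clipped <- clipped + sum(neg); Bn[neg] <- 0 }
    B <- Bn
    steps <- steps + 1L
  }
  st <- partition_biomass(B, f$DOC, f$POC)
  list(B = B, state = st, rates = bact_rates(st, f, p),
       converged = !active, steps = steps, clipped = clipped)
}
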