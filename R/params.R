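#' Model parameters for the bacterial carbon box model
#'
#' Constructs and validates the full parameter set of the bacterial
#' dynamics scheme: maximum uptake rate, Q10 temperature coefficients,
#' half-saturation terms for dissolved (Monod, cubic sigmoid) and
#' particulate (Contois) substrate limitation, the Martin-like depth
#' attenuation of particle-attached activity, respiration, mortality and
#' microzooplankton grazing constants.
#'
#' Defaults are surrogate values in the range used by BFM-family plankton
#' functional type models, chosen so that the oxic steady-state growth
#' efficiency is close to 0.44; only the activity respiration fraction
#' (`gamma_a = 0.5`) is a published model value. `mu_max` is calibrated as
#' a realized community-scale uptake rate (uptake is one-way here, so the
#' substrate-depletion feedback that would tame a physiological maximum of
#' several per day is absent; see the methods vignette). Every default can
#' be overridden.
#'
#' @param mu_max Maximum specific organic carbon uptake rate (d^-1).
#' @param Q10_B Bacterial Q10 temperature coefficient (dimensionless).
#' @param Q10_Z Microzooplankton Q10 temperature coefficient.
#' @param X_DOC DOC half-saturation (mmol C m^-3).
#' @param X_POC Contois half-saturation scale multiplying attached
#'   biomass (dimensionless).
#' @param z0 Reference depth of the depth limitation factor (m).
#' @param b_exp Depth-attenuation exponent (dimensionless, must be <= 0).
#' @param b_B Basal respiration rate (d^-1).
#' @param gamma_a Activity respiration fraction (dimensionless, in [0,1)).
#' @param gamma_o Additional low-oxygen respiration fraction.
#' @param h_o Oxygen half-saturation (mmol O2 m^-3).
#' @param d_B Mortality rate (d^-1).
#' @param r_Z0 Microzooplankton potential specific growth rate (d^-1).
#' @param delta_ZB,delta_ZP Feeding affinities on bacteria/phytoplankton.
#' @param mu_Z Feeding threshold of the capture efficiency (mmol C m^-3).
#' @param h_ZF Half-saturation of total food ingestion (mmol C m^-3).
#' @param T_ref Reference temperature of the Q10 factor (degC).
#' @param oxygen_mode `"low_oxygen_extra"` (default): the extra
#'   respiration term scales with `1 - f_O`, so it appears under low
#'   oxygen; `"as_printed"`: the term scales with `f_O` itself. See the
#'   methods vignette for why both readings exist.
#'
#' @return An object of class `bact_params` (a validated named list).
#' @examples
#' p <- bact_params()
#' p$mu_max
#' bact_params(Q10_B = 2)$Q10_B
#' @export
bact_params <- function(mu_max = 0.15,
                        Q10_B = 2.95,
                        Q10_Z = 2.0,
                        X_DOC = 5,
                        X_POC = 1.0,
                        z0 = 100,
                        b_exp = -0.858,
                        b_B = 0.01,
                        gamma_a = 0.5,
                        gamma_o = 0.2,
                        h_o = 10,
                        d_B = 0.05,
                        r_Z0 = 2.0,
                        delta_ZB = 1,
                        delta_ZP = 1,
                        mu_Z = 0.1,
                        h_ZF = 2.0,
                        T_ref = 10,
                        oxygen_mode = c("low_oxygen_extra", "as_printed")) {
  p <- list(
    mu_max = mu_max, Q10_B = Q10_B, Q10_Z = Q10_Z,
    X_DOC = X_DOC, X_POC = X_POC, z0 = z0, b_exp = b_exp,
    b_B = b_B, gamma_a = gamma_a, gamma_o = gamma_o, h_o = h_o,
    d_B = d_B, r_Z0 = r_Z0, delta_ZB = delta_ZB, delta_ZP = delta_ZP,
    mu_Z = mu_Z, h_ZF = h_ZF, T_ref = T_ref,
    oxygen_mode = match.arg(oxygen_mode)
  )
  class(p) <- "bact_params"
  validate_bact_params(p)
}

#' Validate a `bact_params` object
#'
#' Checks non-negativity of rates and half-saturations, positivity of
#' Q10s and `X_DOC`/`h_ZF`, `gamma_a + gamma_o < 1`, and `b_exp <= 0`.
#'
#' @param p A `bact_params` object.
#' @return `p`, invisibly unchanged, or an error.
#' @export
validate_bact_params <- function(p) {
  stopifnot(inherits(p, "bact_params"))
  num <- p[setdiff(names(p), "oxygen_mode")]
  if (!all(vapply(num, function(x) is.numeric(x) && length(x) == 1 && is.finite(x), logical(1))))
    stop("all parameters must be finite numeric scalars", call. = FALSE)
  if (p$Q10_B <= 0 || p$Q10_Z <= 0) stop("Q10 coefficients must be positive", call. = FALSE)
  if (p$X_DOC <= 0) stop("X_DOC must be positive", call. = FALSE)
  if (p$h_ZF <= 0) stop("h_ZF must be positive", call. = FALSE)
  if (p$b_exp > 0) stop("b_exp must be <= 0", call. = FALSE)
  nonneg <- c("mu_max", "X_POC", "z0", "b_B", "gamma_a", "gamma_o", "h_o",
              "d_B", "r_Z0", "delta_ZB", "delta_ZP", "mu_Z")
  bad <- nonneg[vapply(nonneg, function(k) p[[k]] < 0, logical(1))]
  if (length(bad)) stop("negative parameter(s): ", paste(bad, collapse = ", "), call. = FALSE)
  if (p$gamma_a + p$gamma_o >= 1)
    stop("gamma_a + gamma_o must be < 1 (respired fraction of uptake)", call. = FALSE)
  if (!p$oxygen_mode %in% c("low_oxygen_extra", "as_printed"))
    stop("unknown oxygen_mode", call. = FALSE)
  invisible(p)
}

#' @export
print.bact_params <- function(x, ...) {
  cat("Bacterial box-model parameters\n")
  for (k in setdiff(names(x), "oxygen_mode"))
    cat(sprintf("  %-9s %g\n", k, x[[k]]))
  cat(sprintf("  %-9s %s\n", "oxy.mode", x$oxygen_mode))
  invisible(x)
}

#' Environmental forcing for the bacterial box model
#'
#' Bundles the environmental drivers seen by one (or, vectorised, many)
#' model cells: temperature, substrate pools, dissolved oxygen, grazer
#' and phytoplankton biomass, and depth. All fields recycle to a common
#' length, so whole gridded fields can be passed at once.
#'
#' @param T_c Temperature (degC).
#' @param DOC Dissolved organic carbon (mmol C m^-3).
#' @param POC Particulate organic carbon (mmol C m^-3).
#' @param DO Dissolved oxygen (mmol O2 m^-3).
#' @param Z Microzooplankton carbon biomass (mmol C m^-3).
#' @param P Phytoplankton carbon biomass (mmol C m^-3).
#' @param z Depth (m, >= 0).
#' @return An object of class `bact_forcing` (a list of equal-length
#'   numeric vectors).
#' @examples
#' env_forcing(T_c = 10, DOC = 10, POC = 2, DO = 250, Z = 0.5, P = 1, z = 10)
#' @export
env_forcing <- function(T_c, DOC, POC, DO = 250, Z = 0, P = 0, z = 10) {
  f <- list(T_c = T_c, DOC = DOC, POC = POC, DO = DO, Z = Z, P = P, z = z)
  n <- max(lengths(f))
  f <- lapply(f, function(x) {
    x <- as.numeric(x)
    if (length(x) == n) x else rep_len(x, n)
  })
  if (any(f$DOC < 0, f$POC < 0, f$DO < 0, f$Z < 0, f$P < 0, na.rm = TRUE))
    stop("DOC, POC, DO, Z and P must be non-negative", call. = FALSE)
  if (any(f$z < 0, na.rm = TRUE)) stop("depth z must be >= 0", call. = FALSE)
  structure(f, class = "bact_forcing")
}
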