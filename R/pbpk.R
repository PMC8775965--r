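#' Tumor PBPK parameter set
#'
#' Parameters of the tumor compartment: plasma and lymph flows, transcapillary
#' reflection coefficients, endosomal uptake/catabolism with FcRn-mediated
#' recycling, exponential tumor growth, sub-compartment volumes, and
#' quasi-equilibrium EGFR target binding with internalization of the bound
#' complex. Defaults are the base parameterization for a murine xenograft;
#' `c_egfr = 0` describes a non-binding antibody.
#'
#' The derived target-mediated clearance is `cl_tmd = kint * vi_tu`.
#'
#' @param q_tu Tumor plasma flow (L/min).
#' @param l_tu Tumor lymph flow (L/min).
#' @param clup_tu Endosomal uptake clearance (L/min).
#' @param sigma_v Tumor vascular reflection coefficient, in [0, 1].
#' @param sigma_l Lymph reflection coefficient, in [0, 1].
#' @param cl_tu Catabolic clearance of FcRn-unbound mAb from the endosomal
#'   space (L/min).
#' @param kd_fcrn FcRn-mAb equilibrium dissociation constant (M).
#' @param c_fcrn Endosomal FcRn concentration (M).
#' @param fr Fraction of FcRn-bound mAb recycled to the vascular space.
#' @param kgrowth Tumor growth rate (1/min); all sub-compartment volumes scale
#'   as `exp(kgrowth * t)`.
#' @param vi_tu,ve_tu,vv_tu Initial interstitial, endosomal (endothelial), and
#'   vascular volumes (L).
#' @param kd_egfr mAb-EGFR equilibrium dissociation constant (M).
#' @param kint EGFR internalization rate (1/min).
#' @param c_egfr Total EGFR concentration in the interstitial space (M); 0 for
#'   a non-binding antibody.
#' @return An object of class `tumor_params`.
#' @export
#' @examples
#' tumor_params()                 # non-binding antibody, base values
#' tumor_params(c_egfr = 3.53e-8) # target-binding antibody in an LS174T tumor
tumor_params <- function(q_tu = 1e-4,
                         l_tu = 4e-6,
                         clup_tu = 8.18e-9,
                         sigma_v = 0.734,
                         sigma_l = 0.2,
                         cl_tu = 8.96e-9,
                         kd_fcrn = 7.5e-7,
                         c_fcrn = 1.64e-5,
                         fr = 0.715,
                         kgrowth = 8.08e-5,
                         vi_tu = 1.38e-4,
                         ve_tu = 1.25e-6,
                         vv_tu = 1.75e-5,
                         kd_egfr = 1.5e-10,
                         kint = 1.38e-3,
                         c_egfr = 0) {
  check_number(q_tu, "q_tu", lower = 0)
  check_number(l_tu, "l_tu", lower = 0)
  if (l_tu > q_tu) abort("`l_tu` cannot exceed `q_tu`")
  check_number(clup_tu, "clup_tu", lower = 0)
  check_number(sigma_v, "sigma_v", lower = 0, upper = 1)
  check_number(sigma_l, "sigma_l", lower = 0, upper = 1)
  check_number(cl_tu, "cl_tu", lower = 0)
  check_number(kd_fcrn, "kd_fcrn", lower = 0)
  check_number(c_fcrn, "c_fcrn", lower = 0)
  check_number(fr, "fr", lower = 0, upper = 1)
  check_number(kgrowth, "kgrowth", lower = 0)
  check_number(vi_tu, "vi_tu", lower = 1e-12)
  check_number(ve_tu, "ve_tu", lower = 1e-12)
  check_number(vv_tu, "vv_tu", lower = 1e-12)
  check_number(kd_egfr, "kd_egfr", lower = 0)
  check_number(kint, "kint", lower = 0)
  check_number(c_egfr, "c_egfr", lower = 0)
  structure(
    list(q_tu = q_tu, l_tu = l_tu, clup_tu = clup_tu, sigma_v = sigma_v,
         sigma_l = sigma_l, cl_tu = cl_tu, kd_fcrn = kd_fcrn, c_fcrn = c_fcrn,
         fr = fr, kgrowth = kgrowth, vi_tu = vi_tu, ve_tu = ve_tu,
         vv_tu = vv_tu, kd_egfr = kd_egfr, kint = kint, c_egfr = c_egfr,
         cl_tmd = kint * vi_tu),
    class = "tumor_params"
  )
}

#' @export
print.tumor_params <- function(x, ...) {
  cat("<tumor_params>\n")
  cat(sprintf("  Q = %.3g L/min, L = %.3g L/min, sigma_v = %.3g, sigma_l = %.3g\n",
              x$q_tu, x$l_tu, x$sigma_v, x$sigma_l))
  cat(sprintf("  Clup = %.3g, Cl = %.3g, Cl_tmd = %.3g L/min, FR = %.3g\n",
              x$clup_tu, x$cl_tu, x$cl_tmd, x$fr))
  cat(sprintf("  C_EGFR = %.3g M (KD = %.3g M)\n", x$c_egfr, x$kd_egfr))
  invisible(x)
}

# shallow update of a tumor_params object, revalidating and re-deriving cl_tmd
update_tumor_params <- function(base, ...) {
  new <- utils::modifyList(base[setdiff(names(base), "cl_tmd")], list(...))
  do.call(tumor_params, new)
}

#' Systemic (plasma) antibody disposition
#'
#' The tumor compartment is driven by a plasma forcing function rather than a
#' whole-body model: either a biexponential disposition
#' `Cp(t) = A exp(-alpha t) + B exp(-beta t)` with `A + B` equal to the molar
#' dose divided by the central volume, or a tabulated plasma curve that is
#' linearly interpolated (and held constant beyond its last sample).
#'
#' @param dose Dose in mg/kg.
#' @param bodyweight Body weight in kg (default 0.025, a mouse).
#' @param molecular_weight Antibody molecular weight in g/mol (IgG ~ 1.5e5).
#' @param vc Central (plasma) distribution volume in L.
#' @param frac_a Fraction of the initial concentration on the fast phase.
#' @param alpha,beta Fast/slow disposition rate constants (1/min). Defaults
#'   correspond to distribution and elimination half-lives of roughly 8 h and
#'   4 days, typical of IgG in mice.
#' @param curve Optional tabulated plasma curve: a data frame with columns
#'   `time_min` and `conc_molar`. When supplied it overrides the biexponential.
#' @return An object of class `plasma_pk`.
#' @export
plasma_pk <- function(dose = 1,
                      bodyweight = 0.025,
                      molecular_weight = 1.5e5,
                      vc = 1.2e-3,
                      frac_a = 0.6,
                      alpha = log(2) / 480,
                      beta = log(2) / 5760,
                      curve = NULL) {
  check_number(dose, "dose", lower = 0)
  check_number(bodyweight, "bodyweight", lower = 1e-6)
  check_number(molecular_weight, "molecular_weight", lower = 1)
  check_number(vc, "vc", lower = 1e-9)
  check_number(frac_a, "frac_a", lower = 0, upper = 1)
  check_number(alpha, "alpha", lower = 1e-12)
  check_number(beta, "beta", lower = 1e-12)
  dose_mol <- dose * bodyweight / 1000 / molecular_weight
  c0 <- dose_mol / vc
  if (!is.null(curve)) {
    stopifnot(is.data.frame(curve), all(c("time_min", "conc_molar") %in% names(curve)))
    if (any(curve$conc_molar < 0)) abort("tabulated plasma curve must be non-negative")
    curve <- dplyr::arrange(tibble::as_tibble(curve), .data$time_min)
  }
  structure(
    list(dose = dose, bodyweight = bodyweight,
         molecular_weight = molecular_weight, vc = vc, dose_mol = dose_mol,
         A = frac_a * c0, B = (1 - frac_a) * c0, alpha = alpha, beta = beta,
         curve = curve),
    class = "plasma_pk"
  )
}

#' @export
print.plasma_pk <- function(x, ...) {
  cat("<plasma_pk>\n")
  if (is.null(x$curve)) {
    cat(sprintf("  biexponential: A = %.3g M (alpha = %.3g/min), B = %.3g M (beta = %.3g/min)\n",
                x$A, x$alpha, x$B, x$beta))
  } else {
    cat(sprintf("  tabulated curve with %d samples\n", nrow(x$curve)))
  }
  cat(sprintf("  dose %.3g mg/kg -> %.3g mol\n", x$dose, x$dose_mol))
  invisible(x)
}

#' Plasma concentration forcing function
#'
#' @param plasma A [plasma_pk()] object.
#' @param t Times (minutes, >= 0); vectorized.
#' @return Molar plasma concentration at `t`.
#' @export
#' @examples
#' plasma_forcing(plasma_pk(), c(0, 60, 1440))
plasma_forcing <- function(plasma, t) {
  stopifnot(inherits(plasma, "plasma_pk"))
  if (any(t < 0)) abort("`t` must be non-negative")
  if (is.null(plasma$curve)) {
    plasma$A * exp(-plasma$alpha * t) + plasma$B * exp(-plasma$beta * t)
  } else {
    approx(plasma$curve$time_min, plasma$curve$conc_molar, xout = t, rule = 2)$y
  }
}

#' Closed-form plasma exposure of a biexponential disposition
#'
#' `AUC(0, Inf) = A/alpha + B/beta`.
#'
#' @param plasma A biexponential [plasma_pk()] object.
#' @return AUC in M * min.
#' @export
plasma_auc <- function(plasma) {
  stopifnot(inherits(plasma, "plasma_pk"))
  if (!is.null(plasma$curve)) abort("closed-form AUC requires a biexponential disposition")
  plasma$A / plasma$alpha + plasma$B / plasma$beta
}

#' Quasi-equilibrium bound concentration
#'
#' Solves the equilibrium mass balance for a ligand and receptor given total
#' concentrations and a dissociation constant: the bound concentration is the
#' smaller root of `B^2 - (C + R + KD) B + C R = 0`, evaluated in the
#' numerically stable form `2 C R / (s + sqrt(s^2 - 4 C R))` with
#' `s = C + R + KD`. `KD = 0` returns the stoichiometric limit `min(C, R)`.
#' Used for interstitial mAb-EGFR binding inside the PBPK right-hand side.
#'
#' @param c_total Total ligand (antibody) concentration (M); vectorized.
#' @param r_total Total receptor concentration (M).
#' @param kd Equilibrium dissociation constant (M).
#' @return Bound complex concentration (M), `<= min(c_total, r_total)`.
#' @export
#' @examples
#' egfr_bound(1e-8, 1e-8, 1.5e-10)
egfr_bound <- function(c_total, r_total, kd) {
  stopifnot(all(c_total >= 0), r_total >= 0, kd >= 0)
  s <- c_total + r_total + kd
  disc <- pmax(s^2 - 4 * c_total * r_total, 0)
  out <- rep(0, length(c_total))
  pos <- c_total > 0 & r_total > 0
  out[pos] <- 2 * c_total[pos] * r_total / (s[pos] + sqrt(disc[pos]))
  out
}

# FcRn-bound fraction under receptor excess: endosomal FcRn (~16 uM) vastly
# exceeds tracer-dose mAb, so free receptor is effectively constant and the
# bound fraction is C_FcRn / (C_FcRn + KD), linear in antibody concentration.
fcrn_bound_fraction <- function(tumor) {
  if (tumor$c_fcrn <= 0) return(0)
  tumor$c_fcrn / (tumor$c_fcrn + tumor$kd_fcrn)
}

sim_state_names <- c("amt_plasma", "amt_vascular", "amt_endosomal", "amt_interstitial")
sim_out_names <- c("plasma_conc", "tumor_total_conc", "amt_egfr_bound",
                   "amt_fcrn_bound", "amt_interstitial_free", "amt_endosomal_free")

#' Simulate antibody kinetics in the tumor compartment
#'
#' Integrates the tumor sub-compartment system (vascular, endosomal,
#' interstitial, plus a quasi-equilibrium EGFR-bound pool) driven by the
#' systemic plasma concentration. Transport comprises vascular exchange with
#' plasma (`q_tu`), convective extravasation `(1 - sigma_v) l_tu` and lymphatic
#' drainage `(1 - sigma_l) l_tu`, endosomal uptake `clup_tu` from both the
#' vascular and interstitial spaces with FcRn-bound mAb recycled (`fr` to
#' vascular, `1 - fr` to interstitial) and unbound mAb catabolized at `cl_tu`,
#' and internalization of the EGFR complex at `cl_tmd`. All volumes grow
#' exponentially at `kgrowth`, diluting concentrations. The right-hand side is
#' compiled C code integrated with a stiff solver (deSolve, `lsoda`).
#'
#' @param tumor A [tumor_params()] object.
#' @param plasma A [plasma_pk()] object.
#' @param t_grid Output times in minutes, increasing, starting at 0.
#' @param closed If `TRUE`, the systemic plasma is simulated as a well-mixed
#'   compartment of volume `v_plasma` initially containing the whole dose, and
#'   lymph drainage returns to it. This configuration exists to audit mass
#'   balance; the default (`FALSE`) drives the tumor with the forcing function.
#' @param v_plasma Plasma volume (L) for the closed configuration.
#' @param rtol,atol Solver tolerances. `atol` defaults to `1e-12` times the
#'   molar dose (states are amounts in mol).
#' @return A `pbpk_sim` object wrapping a tibble (`$trajectory`) with columns
#'   `time_min`, `plasma_conc`, `tumor_total_conc`, the four state amounts,
#'   the derived bound/free amounts, and `tumor_volume` (L).
#' @export
#' @examples
#' sim <- simulate_tumor_pbpk(tumor_params(), plasma_pk(), t_grid = seq(0, 8640, by = 60))
#' head(sim$trajectory)
simulate_tumor_pbpk <- function(tumor, plasma, t_grid,
                                closed = FALSE, v_plasma = 1.2e-3,
                                rtol = 1e-8, atol = NULL) {
  stopifnot(inherits(tumor, "tumor_params"), inherits(plasma, "plasma_pk"))
  if (length(t_grid) < 2 || t_grid[1] != 0 || is.unsorted(t_grid, strictly = TRUE)) {
    abort("`t_grid` must be strictly increasing and start at 0")
  }
  dose_scale <- max(plasma$dose_mol, 1e-30)
  atol <- atol %||% (1e-12 * dose_scale)

  tabulated <- !closed && !is.null(plasma$curve)
  parms <- c(
    tumor$q_tu, tumor$l_tu, tumor$clup_tu, tumor$sigma_v, tumor$sigma_l,
    tumor$cl_tu, tumor$fr, fcrn_bound_fraction(tumor), tumor$cl_tmd,
    tumor$kgrowth, tumor$vv_tu, tumor$ve_tu, tumor$vi_tu, tumor$c_egfr,
    tumor$kd_egfr,
    if (is.null(plasma$curve)) plasma$A else 0,
    plasma$alpha,
    if (is.null(plasma$curve)) plasma$B else 0,
    plasma$beta,
    as.numeric(closed), v_plasma, as.numeric(tabulated)
  )
  y0 <- c(if (closed) plasma$dose_mol else 0, 0, 0, 0)
  forcing <- if (tabulated) {
    cv <- plasma$curve
    # extend flat beyond the last sample so the solver never extrapolates
    rbind(as.matrix(cv[, c("time_min", "conc_molar")]),
          c(max(max(cv$time_min) * 2, max(t_grid) + 1), cv$conc_molar[nrow(cv)]))
  } else {
    cbind(c(0, max(t_grid) + 1), c(0, 0))
  }

  out <- deSolve::lsoda(
    y = y0, times = t_grid, func = "tumor_derivs", parms = parms,
    dllname = "dcepbpk", initfunc = "tumor_initmod", initforc = "tumor_initforc",
    forcings = forcing, nout = 6, rtol = rtol, atol = atol, maxsteps = 50000
  )
  diagn <- attr(out, "istate")
  if (!is.null(diagn) && diagn[1] < 0) {
    abort(sprintf("ODE solver failed (istate = %d); see deSolve::diagnostics", diagn[1]))
  }
  out <- as.data.frame(out)
  names(out) <- c("time_min", sim_state_names, sim_out_names)

  # guard against solver undershoot: tolerate (and zero) negatives only when
  # they are numerically negligible relative to the dose
  states <- as.matrix(out[sim_state_names])
  worst <- min(states)
  if (worst < -1e-3 * dose_scale) {
    abort(sprintf("negative state amounts beyond tolerance (min = %g mol)", worst))
  }
  states[states < 0] <- 0
  out[sim_state_names] <- states
  out$tumor_total_conc <- pmax(out$tumor_total_conc, 0)

  ev <- exp(tumor$kgrowth * out$time_min)
  out$tumor_volume <- (tumor$vv_tu + tumor$ve_tu + tumor$vi_tu) * ev
  if (!closed) {
    out$plasma_conc <- plasma_forcing(plasma, out$time_min)
    out$amt_plasma <- NA_real_
  }
  structure(
    list(trajectory = tibble::as_tibble(out), tumor = tumor, plasma = plasma,
         closed = closed, v_plasma = v_plasma),
    class = "pbpk_sim"
  )
}

#' @export
print.pbpk_sim <- function(x, ...) {
  cat("<pbpk_sim>", nrow(x$trajectory), "time points over",
      sprintf("%.3g", max(x$trajectory$time_min) / 1440), "days\n")
  print(utils::head(x$trajectory, 4))
  invisible(x)
}

#' Tumor-to-plasma concentration ratio
#'
#' @param sim A `pbpk_sim` from [simulate_tumor_pbpk()].
#' @param t Time(s) in minutes within the simulated range.
#' @return `tumor_total_conc(t) / plasma_conc(t)`.
#' @export
tumor_to_plasma_ratio <- function(sim, t) {
  stopifnot(inherits(sim, "pbpk_sim"))
  tr <- sim$trajectory
  if (any(t < min(tr$time_min) | t > max(tr$time_min))) {
    abort("`t` outside the simulated range")
  }
  tum <- approx(tr$time_min, tr$tumor_total_conc, xout = t)$y
  pla <- approx(tr$time_min, tr$plasma_conc, xout = t)$y
  if (any(pla <= 0)) abort("plasma concentration is zero at the requested time")
  tum / pla
}

# total tumor concentration at a single time (minutes); used by fitting code
tumor_conc_at <- function(tumor, plasma, t_min, rtol = 1e-8) {
  sim <- simulate_tumor_pbpk(tumor, plasma, t_grid = c(0, t_min), rtol = rtol)
  tail(sim$trajectory$tumor_total_conc, 1)
}

#' The tumor compartment equations as text
#'
#' Writes out the ODE system integrated by [simulate_tumor_pbpk()] for audit.
#'
#' @return A character vector, one equation per element (invisibly printed).
#' @export
pbpk_equations <- function() {
  eq <- c(
    "Concentrations: Cv = Av/Vv(t), Ce = Ae/Ve(t), Ci = Ai/Vi(t); V(t) = V0*exp(kgrowth*t)",
    "EGFR (quasi-equilibrium, totals): B = 2*Ci*Cegfr / (s + sqrt(s^2 - 4*Ci*Cegfr)), s = Ci + Cegfr + KDegfr; Ci_free = Ci - B",
    "FcRn (receptor excess): Cb = f*Ce with f = Cfcrn/(Cfcrn + KDfcrn); Cu = Ce - Cb",
    "dAv/dt = Q*Cp - (Q - L)*Cv - (1 - sigma_v)*L*Cv - Clup*Cv + Clup*FR*Cb",
    "dAe/dt = Clup*Cv + Clup*Ci_free - Clup*Cb - Cl*Cu",
    "dAi/dt = (1 - sigma_v)*L*Cv - (1 - sigma_l)*L*Ci_free - Clup*Ci_free + Clup*(1 - FR)*Cb - Cl_tmd*B",
    "closed configuration only: dAp/dt = (Q - L)*Cv + (1 - sigma_l)*L*Ci_free - Q*Cp, Cp = Ap/Vplasma",
    "Tumor total concentration: (Av + Ae + Ai) / (Vv(t) + Ve(t) + Vi(t))"
  )
  cat(eq, sep = "\n")
  invisible(eq)
}

# Integrate one subject-block per cohort member as a single block-diagonal
# system (3 states each, biexponential forcing only) and return each
# subject's total tumor concentration at its own terminal time (minutes).
# Identical dynamics to simulate_tumor_pbpk; used where many subjects are
# evaluated per likelihood call. All tumor_params must share every field
# except q_tu, l_tu, sigma_v and c_egfr.
simulate_tumor_batch <- function(pars_list, plasma, t_terminal_min, rtol = 1e-8) {
  n <- length(pars_list)
  stopifnot(n >= 1, n <= 512, length(t_terminal_min) == n,
            is.null(plasma$curve))
  p1 <- pars_list[[1]]
  common <- c(p1$clup_tu, p1$sigma_l, p1$cl_tu, p1$fr, fcrn_bound_fraction(p1),
              p1$cl_tmd, p1$kgrowth, p1$vv_tu, p1$ve_tu, p1$vi_tu, p1$kd_egfr,
              plasma$A, plasma$alpha, plasma$B, plasma$beta)
  subj <- vapply(pars_list, function(p) c(p$q_tu, p$l_tu, p$sigma_v, p$c_egfr),
                 numeric(4))
  parms <- c(n, common, as.numeric(subj))
  parms <- c(parms, numeric(16 + 4 * 512 - length(parms)))  # fixed-size C buffer

  times <- sort(unique(c(0, t_terminal_min)))
  out <- deSolve::lsoda(
    y = numeric(3 * n), times = times, func = "tumor_batch_derivs",
    parms = parms, dllname = "dcepbpk", initfunc = "tumor_batch_initmod",
    rtol = rtol, atol = 1e-12 * max(plasma$dose_mol, 1e-30),
    maxsteps = 50000, jactype = "bandint", bandup = 2L, banddown = 2L
  )
  diagn <- attr(out, "istate")
  if (!is.null(diagn) && diagn[1] < 0) {
    abort(sprintf("batched ODE solve failed (istate = %d)", diagn[1]))
  }
  rows <- match(t_terminal_min, times)
  ev <- exp(p1$kgrowth * t_terminal_min)
  vtot <- (p1$vv_tu + p1$ve_tu + p1$vi_tu) * ev
  amt <- vapply(seq_len(n), function(i) {
    sum(pmax(out[rows[i], 1 + (3 * i - 2):(3 * i)], 0))
  }, numeric(1))
  amt / vtot
}
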