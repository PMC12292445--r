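# Ionization-aware solubility of multiprotic drugs.
#
# Ionization is modeled as two independent macroscopic ladders built from
# the printed pKa set: cumulative protonation of the basic groups (in order
# of descending pKa) and cumulative deprotonation of the acidic groups (in
# order of ascending pKa). Mixed (zwitterionic) states are not enumerated;
# for drugs whose basic and acidic pKas are well separated they carry
# negligible population at any single pH.

# Enumerate ionization states. Returns a list with, per state, the
# log10(ionized/neutral) ratio intercept so that
# ratio_i(pH) = 10^(a_i + s_i * pH): bases s = -k, a = sum of k largest base
# pKas; acids s = +k, a = -sum of k smallest acid pKas.
.ionizationStates <- function(groups) {
    bases <- sort(groups$pka[groups$kind == "base"], decreasing = TRUE)
    acids <- sort(groups$pka[groups$kind == "acid"])
    a <- numeric(0); s <- numeric(0); label <- character(0)
    if (length(bases))
        for (k in seq_along(bases)) {
            a <- c(a, sum(bases[seq_len(k)])); s <- c(s, -k)
            label <- c(label, sprintf("cation%+d", k))
        }
    if (length(acids))
        for (k in seq_along(acids)) {
            a <- c(a, -sum(acids[seq_len(k)])); s <- c(s, k)
            label <- c(label, sprintf("anion%+d", -k))
        }
    list(a = a, s = s, label = label)
}

# Ionized/neutral concentration ratios at (scalar) pH, one per state.
.speciesRatios <- function(ph, states) {
    if (!length(states$a)) return(numeric(0))
    10^(states$a + states$s * ph)
}

#' Molar species fractions of an ionizable drug
#'
#' Henderson-Hasselbalch speciation across the macroscopic ionization
#' states implied by a set of acidic/basic pKa values.
#'
#' @param ph medium pH (scalar, in [0, 14]).
#' @param groups data.frame with columns \code{pka} and \code{kind}
#'   ("acid"/"base"); an empty frame yields a purely neutral species.
#' @return Named numeric vector of molar fractions (neutral plus one entry
#'   per cumulative ionization state); sums to 1.
#' @examples
#' fractionIonized(4.24, data.frame(pka = 4.24, kind = "base"))
#' @export
fractionIonized <- function(ph, groups = .emptyGroups()) {
    stopifnot(length(ph) == 1, is.finite(ph), ph >= 0, ph <= 14)
    msgs <- .checkGroups(groups)
    if (length(msgs)) stop(msgs[1])
    states <- .ionizationStates(groups)
    r <- .speciesRatios(ph, states)
    out <- c(1, r) / (1 + sum(r))
    names(out) <- c("neutral", states$label)
    out
}

#' Evaluate a fitted pH-solubility model
#'
#' S(pH) = S0 * (1 + sum over ionization states of min(ratio_i(pH),
#' factor_i - 1)), where ratio_i is the ionized/neutral concentration ratio
#' of state i and factor_i caps that state's solubility gain at factor_i
#' times the intrinsic solubility.
#'
#' @param model a fitted \linkS4class{SolubilityModel} (or a
#'   \linkS4class{DrugSpec} carrying one).
#' @param ph numeric vector of pH values.
#' @return Solubility in mg/mL, same length as \code{ph}.
#' @export
solubilityAtPh <- function(model, ph) {
    if (is(model, "DrugSpec")) model <- model@solubilityModel
    if (is.null(model) || !is(model, "SolubilityModel") || !model@fitted)
        stop("solubility model has not been fitted; call fitSolubilityModel()")
    states <- .ionizationStates(model@groups)
    vapply(ph, function(p) {
        r <- .speciesRatios(p, states)
        model@s0 * (1 + sum(pmin(r, model@factors - 1)))
    }, numeric(1))
}

#' Fit the capped Henderson-Hasselbalch solubility model
#'
#' Two-stage fit. The intrinsic solubility S0 is estimated from the
#' measurements in which the neutral species dominates (neutral molar
#' fraction within a factor 10 of the profile's maximum), as the geometric
#' mean of \code{solubility * neutralFraction} over those points -- the
#' standard way intrinsic solubility is read off a pH-solubility profile
#' without letting strongly ionized points bias it. Given S0, the per-state
#' solubility factors (caps, >= 1) are fitted by least squares on
#' log-solubility with a derivative-free simplex search, bounded below by 1
#' and above by the largest Henderson-Hasselbalch ratio each state attains
#' over the measured pH range (beyond which a cap is unidentifiable).
#'
#' @param measurements data.frame with columns \code{ph} and
#'   \code{solubility} (mg/mL); at least two distinct pH values.
#' @param groups ionizable groups, data.frame(pka, kind).
#' @return A fitted \linkS4class{SolubilityModel}; \code{@fit} holds
#'   per-point relative errors.
#' @export
fitSolubilityModel <- function(measurements, groups = .emptyGroups()) {
    stopifnot(is.data.frame(measurements),
              all(c("ph", "solubility") %in% names(measurements)))
    measurements <- measurements[order(measurements$ph), , drop = FALSE]
    ph <- measurements$ph; sol <- measurements$solubility
    if (length(ph) < 2) stop("at least two solubility measurements required")
    if (!all(is.finite(sol) & sol > 0)) stop("solubilities must be positive")
    if (diff(range(ph)) < 1e-8)
        stop("degenerate pH-solubility profile: all measurements at one pH")
    msgs <- .checkGroups(groups)
    if (length(msgs)) stop(msgs[1])

    states <- .ionizationStates(groups)
    nst <- length(states$a)
    ratios <- if (nst == 0) matrix(0, length(ph), 0)
    else t(matrix(vapply(ph, .speciesRatios, numeric(nst),
                         states = states), nrow = nst))  # [point x state]

    alphaN <- 1 / (1 + rowSums(ratios))
    anchor <- alphaN >= max(alphaN) / 10
    s0 <- exp(mean(log(sol[anchor] * alphaN[anchor])))

    if (nst == 0) {
        mdl <- new("SolubilityModel", s0 = s0, groups = groups,
                   factors = numeric(0), fitted = TRUE,
                   fit = list(relativeError = sol / s0 - 1))
        validObject(mdl)
        return(mdl)
    }

    # caps parameterized as log(factor - 1); bounds per state
    upper <- apply(ratios, 2, max) * 10
    needed <- max(sol) / s0
    start <- pmin(pmax(apply(ratios, 2, max), 1e-3), needed)
    obj <- function(lc) {
        caps <- exp(lc)
        pred <- log(s0) + log1p(colSums(pmin(t(ratios), caps)))
        sum((pred - log(sol))^2)
    }
    par0 <- log(start)
    if (nst > 1)    # simplex first: the capped objective is only piecewise
        par0 <- stats::optim(par0, obj, method = "Nelder-Mead",
                             control = list(maxit = 5000,
                                            reltol = 1e-14))$par
    opt <- stats::optim(par0, obj, method = "L-BFGS-B",
                        lower = log(1e-9), upper = log(upper),
                        control = list(maxit = 500, factr = 1e4))
    factors <- 1 + exp(opt$par)
    mdl <- new("SolubilityModel", s0 = s0, groups = groups,
               factors = factors, fitted = TRUE, fit = list())
    pred <- solubilityAtPh(mdl, ph)
    mdl@fit <- list(relativeError = pred / sol - 1,
                    sse = opt$value, convergence = opt$convergence)
    validObject(mdl)
    mdl
}

#' Bile-salt solubilization of a lipophilic drug
#'
#' Micellar solubility enhancement from the Mithani-style lipophilicity
#' correlation: the micelle-water partition coefficient is
#' K = 10^(2.23 + 0.61 logP), and the enhanced solubility is
#' \code{aqueous * (1 + K * phi)} with \code{phi} the micellar volume
#' fraction of sodium taurocholate (MW 537.7 g/mol, partial specific volume
#' 0.778 mL/g) at the given bile-salt concentration.
#'
#' @param logP drug log10 partition coefficient.
#' @param bileSaltConc bile-salt concentration, mM.
#' @param aqueousSolubility mg/mL.
#' @return Enhanced solubility, mg/mL (equal to \code{aqueousSolubility}
#'   when \code{bileSaltConc} is zero).
#' @export
bileSaltEnhancement <- function(logP, bileSaltConc, aqueousSolubility) {
    stopifnot(all(bileSaltConc >= 0))
    k <- 10^(2.23 + 0.61 * logP)
    phi <- bileSaltConc * 1e-3 * 537.7 * 0.778 / 1000  # volume fraction
    aqueousSolubility * (1 + k * phi)
}

#' Aqueous diffusion coefficient from molecular weight
#'
#' Power-law correlation D = 9.9e-5 * MW^(-0.453) cm^2/s, the standard
#' molecular-weight scaling used by mechanistic absorption software for
#' small-molecule diffusivity in water at 37 C.
#'
#' @param mw molecular weight, g/mol.
#' @return Diffusion coefficient, cm^2/s.
#' @examples
#' diffusionCoefficientFromMW(488.61)  # ~0.599e-5
#' @export
diffusionCoefficientFromMW <- function(mw) {
    stopifnot(all(is.finite(mw) & mw > 0))
    9.9e-5 * mw^(-0.453)
}

# Effective diffusion coefficient of a drug, cm^2/s.
.drugDiffusionCoeff <- function(drug) {
    if (is.finite(drug@diffusionCoeff)) drug@diffusionCoeff
    else diffusionCoefficientFromMW(drug@mw)
}
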