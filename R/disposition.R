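# Linear mammillary disposition: simulation, terminal half-life,
# compartmental fitting from concentration-time data, and NCA metrics.

# Rate matrix of the mammillary system (central compartment first).
.dispositionMatrix <- function(params) {
    k10 <- params@cl / params@vc
    matrix(c(-(k10 + params@k12 + params@k13), params@k21, params@k31,
             params@k12, -params@k21, 0,
             params@k13, 0, -params@k31),
           nrow = 3, byrow = TRUE)
}

# Central-compartment concentration (ng/mL) for an IV bolus, via eigen
# decomposition; `times` in h.
.bolusConc <- function(params, dose, times) {
    m <- .dispositionMatrix(params)
    e <- eigen(m)
    w <- solve(e$vectors, c(dose, 0, 0))
    amt <- Re(e$vectors[1, ] %*% (w * exp(outer(e$values, times))))
    as.numeric(amt) / (params@vc * params@bodyWeight) * 1000
}

# Central concentration (ng/mL) for first-order oral input with rate ka
# (1/h) of a bioavailable amount fDose = F * dose (mg) into the central
# compartment.
.oralFirstOrderConc <- function(params, fDose, ka, times) {
    m <- .dispositionMatrix(params)
    e <- eigen(m)
    w <- solve(e$vectors, c(1, 0, 0))
    lam <- e$values
    g <- vapply(times, function(t)
        sum(Re(e$vectors[1, ] * w * (exp(lam * t) - exp(-ka * t)) /
                   (lam + ka))), numeric(1))
    ka * fDose * g / (params@vc * params@bodyWeight) * 1000
}

#' Simulate systemic disposition for an arbitrary input flux
#'
#' Integrates the linear 1-3 compartment disposition ODEs for an IV bolus
#' and/or a time-varying infusion flux into the central compartment, and
#' returns the plasma concentration-time profile (central amount divided by
#' Vc x body weight, in ng/mL).
#'
#' @param params a \linkS4class{DispositionParams}.
#' @param bolus IV bolus dose, mg, given at t = 0.
#' @param input optional function of time (h) returning the flux into the
#'   central compartment, mg/h.
#' @param duration h.
#' @param dt output step, h.
#' @return data.frame with columns \code{t_h} and \code{conc_ng_mL}.
#' @export
simulateDisposition <- function(params, bolus = 0, input = NULL,
                                duration = 24, dt = 0.01) {
    stopifnot(is(params, "DispositionParams"), bolus >= 0)
    times <- seq(0, duration, by = dt)
    if (is.null(input)) {
        conc <- .bolusConc(params, bolus, times)
        return(data.frame(t_h = times, conc_ng_mL = conc))
    }
    stopifnot(is.function(input))
    m <- .dispositionMatrix(params)
    rhs <- function(t, y, p)
        list(as.numeric(m %*% y) + c(input(t), 0, 0))
    out <- deSolve::lsoda(c(bolus, 0, 0), times, rhs, parms = NULL,
                          rtol = 1e-10, atol = 1e-12)
    data.frame(t_h = times,
               conc_ng_mL = out[, 2] / (params@vc * params@bodyWeight) * 1000)
}

#' Terminal elimination half-life
#'
#' ln(2) divided by the smallest-magnitude eigenvalue of the disposition
#' rate matrix.
#'
#' @param params a \linkS4class{DispositionParams}.
#' @return Half-life, h.
#' @examples
#' p <- dispositionParams(cl = 0.925, vc = 0.8, k12 = 3.09, k21 = 2.1,
#'                        k13 = 0.448, k31 = 0.25)
#' terminalHalfLife(p)  # ~4.43
#' @export
terminalHalfLife <- function(params) {
    stopifnot(is(params, "DispositionParams"))
    if (params@cl <= 0 || params@vc <= 0)
        stop("clearance and central volume must be positive")
    lam <- eigen(.dispositionMatrix(params), only.values = TRUE)$values
    lam <- Re(lam[abs(Re(lam)) > 1e-12])
    log(2) / min(abs(lam))
}

# Strip a sum of k exponentials off a positive decaying curve (curve
# peeling / feathering); returns list(lambda, amp) sorted ascending lambda.
.peelExponentials <- function(t, c, k) {
    lambda <- numeric(0); amp <- numeric(0)
    rem <- c
    hi <- length(t)
    for (i in seq_len(k)) {
        ok <- which(rem[seq_len(hi)] > 0)
        if (length(ok) < 2) break
        m <- max(3L, ceiling(length(ok) / 3))
        idx <- utils::tail(ok, m)
        fit <- stats::lm(log(rem[idx]) ~ t[idx])
        lam <- -unname(stats::coef(fit)[2])
        if (!is.finite(lam) || lam <= 0) lam <- 1 / max(t[idx])
        a <- exp(unname(stats::coef(fit)[1]))
        lambda <- c(lambda, lam); amp <- c(amp, a)
        rem <- rem - a * exp(-lam * t)
        hi <- min(idx) - 1L
        if (hi < 2) break
    }
    while (length(lambda) < k) {
        lambda <- c(lambda, max(lambda) * 4)
        amp <- c(amp, max(c) / k)
    }
    o <- order(lambda)
    list(lambda = lambda[o], amp = amp[o])
}

# Convert a fitted sum of exponentials (IV bolus) to micro-constants.
# lambda ascending; amps > 0; returns list(k10, k12, k21, k13, k31, c0).
.exponentialsToMicro <- function(lambda, amp, nc) {
    c0 <- sum(amp)
    f <- amp / c0
    if (nc == 1)
        return(list(k10 = lambda[1], k12 = 0, k21 = 0, k13 = 0, k31 = 0,
                    c0 = c0))
    if (nc == 2) {
        k21 <- f[1] * (lambda[2] - lambda[1]) + lambda[1]
        k10 <- lambda[1] * lambda[2] / k21
        k12 <- sum(lambda) - k21 - k10
        return(list(k10 = k10, k12 = max(k12, 1e-8), k21 = k21, k13 = 0,
                    k31 = 0, c0 = c0))
    }
    # three compartments: the transfer-function numerator
    # N(s) = (s + k21)(s + k31) satisfies N(-lam_i) = f_i * prod_{j != i}
    # (lam_j - lam_i); fit the monic quadratic through those three values.
    y <- vapply(1:3, function(i)
        f[i] * prod(lambda[-i] - lambda[i]), numeric(1))
    # y_i = lam_i^2 - p lam_i + q
    A <- cbind(-lambda, 1)
    pq <- stats::lm.fit(A, y - lambda^2)$coefficients
    p <- pq[1]; q <- pq[2]
    disc <- p^2 - 4 * q
    if (disc < 0) disc <- 0
    k21 <- (p + sqrt(disc)) / 2
    k31 <- (p - sqrt(disc)) / 2
    k21 <- max(k21, 1e-8); k31 <- max(k31, 1e-8)
    k10 <- prod(lambda) / (k21 * k31)
    a2 <- lambda[1] * lambda[2] + lambda[1] * lambda[3] +
        lambda[2] * lambda[3]
    s1 <- sum(lambda) - k10 - k21 - k31            # k12 + k13
    s2 <- a2 - k10 * (k21 + k31) - k21 * k31       # k31 k12 + k21 k13
    k12 <- (s2 - k21 * s1) / (k31 - k21)
    k13 <- s1 - k12
    list(k10 = max(k10, 1e-8), k12 = max(k12, 1e-8),
         k21 = k21, k13 = max(k13, 1e-8), k31 = k31, c0 = c0)
}

#' Fit compartmental disposition parameters from plasma data
#'
#' Fits a linear 1-3 compartment model to an IV-bolus concentration-time
#' profile by curve peeling followed by weighted (1/C) Levenberg-Marquardt
#' least squares on the compartmental solution, with the micro-constants
#' recovered analytically from the exponential phases. When an oral profile
#' is also supplied, a first-order absorption rate constant and apparent
#' bioavailability are estimated in a second stage with the disposition
#' fixed.
#'
#' @param ivProfile data.frame(t_h, conc_ng_mL) after an IV bolus.
#' @param dose IV dose, mg.
#' @param oralProfile optional data.frame(t_h, conc_ng_mL) after an oral
#'   dose.
#' @param oralDose mg, required with \code{oralProfile}.
#' @param nCompartments 1, 2 or 3.
#' @param bodyWeight kg.
#' @return A \linkS4class{DispositionParams}; \code{@fit} carries residual
#'   diagnostics and, if fitted, the oral \code{ka} (1/h) and apparent
#'   bioavailability.
#' @export
fitDisposition <- function(ivProfile, dose, oralProfile = NULL,
                           oralDose = NULL, nCompartments = 3,
                           bodyWeight = 70) {
    stopifnot(nCompartments %in% 1:3, dose > 0)
    t <- ivProfile$t_h; c <- ivProfile$conc_ng_mL
    keep <- is.finite(c) & c > 0
    t <- t[keep]; c <- c[keep]
    if (length(t) < 2 * nCompartments + 1)
        stop("need at least ", 2 * nCompartments + 1,
             " positive observations to fit ", nCompartments,
             " compartments")
    peel <- .peelExponentials(t, c, nCompartments)
    ctl <- minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                      ptol = 1e-15)
    w <- 1 / sqrt(c)   # residuals weighted 1/C in the squared objective

    # refine the exponential mixture, then convert to micro-constants
    k <- nCompartments
    mixRes <- function(par)
        (as.numeric(exp(par[seq_len(k)]) %*%
                        exp(-exp(par[k + seq_len(k)]) %o% t)) - c) * w
    mix <- try(minpack.lm::nls.lm(
        par = c(log(pmax(peel$amp, 1e-9)), log(peel$lambda)),
        fn = mixRes, control = ctl), silent = TRUE)
    if (!inherits(mix, "try-error")) {
        amp <- exp(mix$par[seq_len(k)])
        lambda <- exp(mix$par[k + seq_len(k)])
        o <- order(lambda)
        amp <- amp[o]; lambda <- lambda[o]
    } else {
        amp <- peel$amp; lambda <- peel$lambda
    }
    micro <- .exponentialsToMicro(lambda, amp, nCompartments)
    vc <- 1000 * dose / micro$c0 / bodyWeight      # L/kg

    # final polish directly on the micro-constant model
    microConc <- function(logp) {
        pp <- exp(logp)
        prm <- dispositionParams(cl = pp[1] * pp[2], vc = pp[2],
                                 k12 = if (nCompartments >= 2) pp[3] else 0,
                                 k21 = if (nCompartments >= 2) pp[4] else 0,
                                 k13 = if (nCompartments >= 3) pp[5] else 0,
                                 k31 = if (nCompartments >= 3) pp[6] else 0,
                                 bodyWeight = bodyWeight)
        .bolusConc(prm, dose, t)
    }
    p0 <- log(c(micro$k10, vc, micro$k12, micro$k21, micro$k13,
                micro$k31)[seq_len(2 * nCompartments)])
    fit <- try(minpack.lm::nls.lm(
        par = p0, fn = function(par) (microConc(par) - c) * w,
        control = ctl), silent = TRUE)
    if (inherits(fit, "try-error")) {
        pp <- exp(p0)
        diag <- list(converged = FALSE, message = as.character(fit))
    } else {
        pp <- exp(fit$par)
        diag <- list(converged = fit$info %in% 1:4,
                     message = fit$message,
                     weightedResiduals = fit$fvec)
    }
    params <- dispositionParams(
        cl = pp[1] * pp[2], vc = pp[2],
        k12 = if (nCompartments >= 2) pp[3] else 0,
        k21 = if (nCompartments >= 2) pp[4] else 0,
        k13 = if (nCompartments >= 3) pp[5] else 0,
        k31 = if (nCompartments >= 3) pp[6] else 0,
        bodyWeight = bodyWeight)
    params@fit <- diag

    if (!is.null(oralProfile)) {
        stopifnot(!is.null(oralDose))
        to <- oralProfile$t_h; co <- oralProfile$conc_ng_mL
        ok <- is.finite(co) & co > 0
        to <- to[ok]; co <- co[ok]
        oralRes <- function(par)
            (.oralFirstOrderConc(params, exp(par[2]) * oralDose,
                                 exp(par[1]), to) - co) / sqrt(co)
        ofit <- try(minpack.lm::nls.lm(par = c(log(1), log(0.5)),
                                       fn = oralRes, control = ctl),
                    silent = TRUE)
        if (!inherits(ofit, "try-error")) {
            params@fit$ka <- exp(ofit$par[1])
            params@fit$fApparent <- exp(ofit$par[2])
        }
    }
    params
}

#' Non-compartmental pharmacokinetic metrics
#'
#' Cmax/Tmax from the grid maximum, AUC0-t by linear trapezoid, terminal
#' slope lambda_z by log-linear regression over the last third of the
#' post-Tmax points (minimum 3), and AUC0-inf = AUC0-t + Clast/lambda_z.
#'
#' @param profile data.frame with columns \code{t_h} and \code{conc_ng_mL},
#'   or a \linkS4class{SimulationResult}.
#' @return list with cmax (ng/mL), tmax (h), auc0t, auc0inf (ng h/mL),
#'   lambdaZ (1/h). \code{auc0inf} and \code{lambdaZ} are \code{NA} when the
#'   terminal slope is not estimable.
#' @export
pkMetrics <- function(profile) {
    if (is(profile, "SimulationResult")) profile <- plasmaProfile(profile)
    t <- profile$t_h; c <- profile$conc_ng_mL
    stopifnot(length(t) >= 3, all(diff(t) > 0), all(c >= 0, na.rm = TRUE))
    imax <- which.max(c)
    cmax <- c[imax]; tmax <- t[imax]
    n <- length(t)
    auc0t <- sum(diff(t) * (c[-1] + c[-n]) / 2)
    post <- if (imax < n) seq.int(imax + 1L, n) else integer(0)
    post <- post[c[post] > 0]
    lambdaZ <- NA_real_; auc0inf <- NA_real_
    if (length(post) >= 3) {
        idx <- utils::tail(post, max(3L, ceiling(length(post) / 3)))
        sl <- stats::coef(stats::lm(log(c[idx]) ~ t[idx]))[2]
        if (is.finite(sl) && sl < 0) {
            lambdaZ <- -unname(sl)
            auc0inf <- auc0t + c[n] / lambdaZ
        }
    }
    list(cmax = cmax, tmax = tmax, auc0t = auc0t, auc0inf = auc0inf,
         lambdaZ = lambdaZ)
}
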