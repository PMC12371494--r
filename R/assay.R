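#' Normalize a raw competition signal to percent of the DMSO control
#'
#' @param raw_signal raw signal(s) at the test condition; technical
#'   replicates are averaged.
#' @param dmso_control_signal vehicle-control signal (averaged if several
#'   replicates are given); must be positive.
#' @return Percent residual signal (100 = no displacement).
#' @examples
#' normalize_residual(c(40, 60), 100)  # 50
#' @export
normalize_residual <- function(raw_signal, dmso_control_signal) {
  ctrl <- mean(dmso_control_signal)
  if (!is.finite(ctrl) || ctrl <= 0) {
    stop("DMSO control signal must be positive")
  }
  100 * mean(raw_signal) / ctrl
}

#' Single-dose triage of a residual-signal panel
#'
#' Compounds whose residual signal at the screening concentration is
#' strictly below the cutoff (default 60%) advance to dose-response
#' follow-up; a compound at exactly the cutoff does not advance.
#'
#' @param residuals named numeric vector of percent residual signals, or
#'   a `data.frame` with columns `compound` and `residual`.
#' @param cutoff percent cutoff (default 60).
#' @return Character vector of advancing compound identifiers.
#' @export
triage <- function(residuals, cutoff = 60) {
  if (is.data.frame(residuals)) {
    residuals <- stats::setNames(residuals$residual, residuals$compound)
  }
  names(residuals)[residuals < cutoff]
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of
#' `signal = bottom + (top - bottom) / (1 + (conc / IC50)^hill)`
#' by Levenberg-Marquardt (via `minpack.lm`), parameterised in
#' `log10(IC50)` for stability.  The IC50 is the concentration halving
#' the signal window; its confidence interval comes from the fit
#' covariance on the log scale.  Fits that do not converge, or whose IC50
#' falls outside the tested concentration range, are returned flagged
#' (`determined = FALSE` with a reason) rather than dropped — the
#' "IC50 could not be determined" outcome.
#'
#' @param panel `data.frame` with columns `conc_M` and `signal` (other
#'   columns are carried along as metadata); at least 4 distinct
#'   concentrations.
#' @param fix_hill optional fixed Hill slope (default `NULL`: free).
#' @param conf_level confidence level for the IC50 interval.
#' @return An object of class `ic50_fit`: list with `ic50`, `ic50_ci`,
#'   `hill`, `top`, `bottom`, `determined`, `reason`, `converged`,
#'   `residual_se`, and `fit` (the underlying `nls` object or `NULL`).
#' @examples
#' panel <- generate_dose_response(assay_gen_spec(true_ic50 = 1.1e-5,
#'                                                noise_cv = 0))
#' fit_dose_response(panel)$ic50
#' @export
fit_dose_response <- function(panel, fix_hill = NULL, conf_level = 0.95) {
  stopifnot(all(c("conc_M", "signal") %in% names(panel)))
  if (length(unique(panel$conc_M)) < 4L) {
    stop("need at least 4 distinct concentrations for a dose-response fit")
  }
  flagged <- function(reason) {
    structure(list(ic50 = NA_real_, ic50_ci = c(NA_real_, NA_real_),
                   hill = NA_real_, top = NA_real_, bottom = NA_real_,
                   determined = FALSE, reason = reason, converged = FALSE,
                   residual_se = NA_real_, fit = NULL),
              class = "ic50_fit")
  }
  mean_by_conc <- tapply(panel$signal, panel$conc_M, mean)
  top0 <- max(mean_by_conc)
  bottom0 <- min(mean_by_conc)
  mid <- (top0 + bottom0) / 2
  ic50_0 <- as.numeric(names(mean_by_conc))[which.min(abs(mean_by_conc - mid))]
  dat <- data.frame(conc = panel$conc_M, signal = panel$signal)
  fit <- if (is.null(fix_hill)) {
    try(minpack.lm::nlsLM(
      signal ~ bottom + (top - bottom) / (1 + 10^(hill * (log10(conc) - lic50))),
      data = dat,
      start = list(lic50 = log10(ic50_0), hill = 1, top = top0, bottom = bottom0),
      control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  } else {
    try(minpack.lm::nlsLM(
      signal ~ bottom + (top - bottom) /
        (1 + 10^(fix_hill * (log10(conc) - lic50))),
      data = dat,
      start = list(lic50 = log10(ic50_0), top = top0, bottom = bottom0),
      control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  }
  if (inherits(fit, "try-error")) {
    return(flagged("nonlinear regression did not converge"))
  }
  cf <- stats::coef(fit)
  ic50 <- 10^cf[["lic50"]]
  hill <- if (is.null(fix_hill)) cf[["hill"]] else fix_hill
  se <- tryCatch(sqrt(diag(stats::vcov(fit)))[["lic50"]],
                 error = function(e) NA_real_)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- if (is.na(se)) c(NA_real_, NA_real_) else 10^(cf[["lic50"]] + c(-z, z) * se)
  out <- structure(
    list(ic50 = ic50, ic50_ci = ci, hill = hill,
         top = cf[["top"]], bottom = cf[["bottom"]],
         determined = TRUE, reason = NA_character_, converged = TRUE,
         residual_se = stats::sigma(fit), fit = fit),
    class = "ic50_fit"
  )
  rng <- range(panel$conc_M)
  if (ic50 < rng[1L] || ic50 > rng[2L]) {
    out$determined <- FALSE
    out$reason <- sprintf(
      "IC50 could not be determined: fitted value %.3g M lies outside the tested range [%.3g, %.3g] M",
      ic50, rng[1L], rng[2L])
  }
  if (out$top - out$bottom <= 0) {
    out$determined <- FALSE
    out$reason <- "IC50 could not be determined: no signal window (top <= bottom)"
  }
  out
}

#' @export
print.ic50_fit <- function(x, ...) {
  if (x$determined) {
    cat(sprintf("IC50 = %.3g M (%.0f%% CI %.3g - %.3g), Hill = %.2f\n",
                x$ic50, 95, x$ic50_ci[1], x$ic50_ci[2], x$hill))
  } else {
    cat("flagged:", x$reason, "\n")
  }
  invisible(x)
}

#' Probe parameters for the Cheng-Prusoff conversion
#'
#' Defaults are the fluorescein-labelled m6A-DNA probe conditions of the
#' FP competition assay: 3 nM probe, with probe dissociation constants of
#' 5 nM (DF2), 7 nM (DC2), and 5 nM (DC1).
#'
#' @param probe_concentration probe concentration `[L]` in M.
#' @param probe_kd named vector of probe Kd values per protein, in M.
#' @return An object of class `probe_spec`.
#' @export
probe_spec <- function(probe_concentration = 3e-9,
                       probe_kd = c(DF2 = 5e-9, DC2 = 7e-9, DC1 = 5e-9)) {
  stopifnot(probe_concentration > 0, all(probe_kd > 0))
  structure(list(probe_concentration = probe_concentration,
                 probe_kd = probe_kd),
            class = "probe_spec")
}

#' Convert a competition IC50 to Kd by the Cheng-Prusoff equation
#'
#' `Kd = IC50 / (1 + [L] / Kd_probe)`.  With the default probe (3 nM,
#' Kd 5 nM on DF2) the DF2 divisor is `1 + 3/5 = 1.6`.
#'
#' @param ic50 observed IC50 in M (vectorised).
#' @param probe a [probe_spec()].
#' @param protein protein the IC50 was measured on; must have a probe Kd.
#' @return Kd in M.
#' @examples
#' cheng_prusoff(16e-6, protein = "DF2")  # 1e-05
#' @export
cheng_prusoff <- function(ic50, probe = probe_spec(), protein = "DF2") {
  if (!protein %in% names(probe$probe_kd)) {
    stop("no probe Kd specified for protein '", protein, "'")
  }
  ic50 / (1 + probe$probe_concentration / probe$probe_kd[[protein]])
}

#' Ligand efficiency from an IC50
#'
#' `LE = -dG / HAC ~ -RT ln(IC50) / HAC`, in kcal/(mol * heavy atom),
#' with `R = 1.987e-3` kcal/(mol K).  An IC50 of 1 M or more gives a
#' non-positive LE, which is flagged as non-physical for this assay
#' range.
#'
#' @param ic50 IC50 in M (vectorised).
#' @param hac heavy-atom (non-hydrogen) count, at least 1.
#' @param temperature temperature in K (default 300).
#' @return LE in kcal/(mol * HAC).
#' @examples
#' ligand_efficiency(18e-6, hac = 11)  # about 0.59
#' @export
ligand_efficiency <- function(ic50, hac, temperature = 300) {
  stopifnot(all(ic50 > 0), all(hac >= 1))
  R <- 1.987e-3  # kcal/(mol K)
  le <- -R * temperature * log(ic50) / hac
  if (any(ic50 >= 1)) {
    warning("IC50 >= 1 M gives non-positive ligand efficiency; ",
            "flagged as non-physical for this assay range")
  }
  le
}

#' Selectivity fold-ratios relative to a reference protein
#'
#' `ratio[p] = Kd[p] / Kd[reference]`; values above 1 mean the compound
#' prefers the reference protein.  Censored affinities (lower bounds,
#' e.g. "Kd > 400 uM") propagate as censored (lower-bound) ratios.
#'
#' @param kds named numeric vector of Kd values in M, or a `data.frame`
#'   with columns `protein`, `kd`, and optionally `censored` (logical;
#'   `TRUE` means the Kd is a lower bound).
#' @param reference reference protein (default `"DF2"`); its Kd must be
#'   present and uncensored.
#' @return A `data.frame` with columns `protein`, `ratio`, `censored`,
#'   and `label` (e.g. `"23.2"` or `">308"`), excluding the reference.
#' @examples
#' selectivity(c(DF2 = 3.8e-6, DC2 = 88e-6, DC1 = 32e-6))
#' @export
selectivity <- function(kds, reference = "DF2") {
  if (!is.data.frame(kds)) {
    kds <- data.frame(protein = names(kds), kd = unname(kds),
                      censored = FALSE, stringsAsFactors = FALSE)
  }
  if (is.null(kds$censored)) kds$censored <- FALSE
  i_ref <- match(reference, kds$protein)
  if (is.na(i_ref)) stop("reference protein '", reference, "' has no Kd")
  if (kds$censored[i_ref]) {
    stop("reference Kd is censored; fold-ratios would be undefined")
  }
  out <- kds[-i_ref, , drop = FALSE]
  out$ratio <- out$kd / kds$kd[i_ref]
  out$label <- ifelse(out$censored,
                      paste0(">", signif(out$ratio, 3)),
                      as.character(signif(out$ratio, 3)))
  rownames(out) <- NULL
  out[, c("protein", "ratio", "censored", "label")]
}

#' Screening hit-rate summary
#'
#' A compound counts as active when its IC50 could be determined.  The
#' hit rate is `100 * actives / tested`, rounded to the nearest integer
#' percent; a per-campaign breakdown is included when a `campaign` column
#' is present.
#'
#' @param results `data.frame` with columns `compound`, `active`
#'   (logical), and optionally `campaign`.
#' @return A list with `tested`, `actives`, `hit_rate_percent`, and
#'   (when campaigns are given) `by_campaign`.
#' @examples
#' screen_summary(data.frame(compound = 1:47, active = rep(c(TRUE, FALSE),
#'                                                         c(6, 41))))
#' @export
screen_summary <- function(results) {
  if (nrow(results) == 0L) stop("no compounds tested")
  summ <- function(df) {
    list(tested = nrow(df), actives = sum(df$active),
         hit_rate_percent = round(100 * sum(df$active) / nrow(df)))
  }
  out <- summ(results)
  if (!is.null(results$campaign)) {
    out$by_campaign <- lapply(split(results, results$campaign), summ)
  }
  out
}

#' Fit a whole assay panel into an affinity table
#'
#' Groups a long-format panel by compound, protein, and assay, fits each
#' dose-response, converts FP IC50s to Kd by Cheng-Prusoff where probe
#' parameters exist, and attaches ligand efficiency where heavy-atom
#' counts are supplied.  Every input group appears in the output with an
#' explicit status; flagged fits are never dropped.
#'
#' @param panel `data.frame` with columns `compound`, `protein`, `assay`,
#'   `conc_M`, `signal`, `replicate`.
#' @param probe a [probe_spec()] for Kd conversion of FP data.
#' @param hac optional named vector (or `data.frame` with `compound`,
#'   `hac`) of heavy-atom counts.
#' @param fix_hill optional fixed Hill slope passed to
#'   [fit_dose_response()].
#' @return A `data.frame` with one row per compound x protein x assay:
#'   `compound`, `protein`, `assay`, `ic50_M`, `ic50_lo`, `ic50_hi`,
#'   `kd_M`, `hill`, `le`, `status`.
#' @export
fit_affinity_panel <- function(panel, probe = probe_spec(), hac = NULL,
                               fix_hill = NULL) {
  if (is.data.frame(hac)) hac <- stats::setNames(hac$hac, hac$compound)
  groups <- split(panel, interaction(panel$compound, panel$protein,
                                     panel$assay, drop = TRUE))
  rows <- lapply(groups, function(g) {
    fit <- fit_dose_response(g, fix_hill = fix_hill)
    kd <- NA_real_
    if (fit$determined && g$assay[1L] == "FP" &&
        g$protein[1L] %in% names(probe$probe_kd)) {
      kd <- cheng_prusoff(fit$ic50, probe, g$protein[1L])
    }
    le <- NA_real_
    if (fit$determined && !is.null(hac) && g$compound[1L] %in% names(hac)) {
      le <- ligand_efficiency(fit$ic50, hac[[g$compound[1L]]])
    }
    data.frame(compound = g$compound[1L], protein = g$protein[1L],
               assay = g$assay[1L], ic50_M = fit$ic50,
               ic50_lo = fit$ic50_ci[1L], ic50_hi = fit$ic50_ci[2L],
               kd_M = kd, hill = fit$hill, le = le,
               status = if (fit$determined) "ok" else fit$reason,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read an assay panel CSV
#'
#' Expects columns `compound`, `protein`, `assay`, `conc_M`, `signal`,
#' `replicate`.
#'
#' @param file path to the CSV.
#' @return A `data.frame`.
#' @export
read_assay_panel <- function(file) {
  panel <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("compound", "protein", "assay", "conc_M", "signal", "replicate")
  missing <- setdiff(need, names(panel))
  if (length(missing) > 0L) {
    stop("assay panel is missing column(s): ", paste(missing, collapse = ", "))
  }
  panel
}
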