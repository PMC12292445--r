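# Configuration and tabular IO shared by all stages. Drug files are YAML
# with the units conventionally printed in model input tables; values are
# converted to canonical internal units at the point of use, never in the
# file.

.DRUG_CONFIG_KEYS <- c(
    name = TRUE, molecular_weight_g_mol = TRUE, logp = TRUE,
    pka = TRUE, solubility_mg_ml = TRUE,
    peff_cm_s = TRUE, particle_diameter_um = FALSE,
    particle_density_g_ml = FALSE, precipitation_time_s = FALSE,
    diffusion_coeff_cm2_s = FALSE,
    first_pass_effect_percent = FALSE, clearance_l_h_kg = TRUE,
    central_volume_l_kg = TRUE, k12_1_h = FALSE, k21_1_h = FALSE,
    k13_1_h = FALSE, k31_1_h = FALSE, body_weight_kg = FALSE,
    blood_plasma_ratio = FALSE, fraction_unbound_percent = FALSE)

#' Read a drug parameter file
#'
#' Parses a YAML drug configuration, rejects unknown keys, checks mandatory
#' fields, and returns a validated \linkS4class{DrugSpec} (with the
#' pH-solubility model fitted).
#'
#' @param path file path.
#' @return A \linkS4class{DrugSpec}.
#' @export
readDrugConfig <- function(path) {
    if (!file.exists(path)) stop("drug config not found: ", path)
    cfg <- yaml::read_yaml(path)
    unknown <- setdiff(names(cfg), names(.DRUG_CONFIG_KEYS))
    if (length(unknown))
        stop("unknown keys in ", path, ": ",
             paste(unknown, collapse = ", "))
    missing <- setdiff(names(.DRUG_CONFIG_KEYS)[.DRUG_CONFIG_KEYS],
                       names(cfg))
    if (length(missing))
        stop("missing mandatory fields in ", path, ": ",
             paste(missing, collapse = ", "))
    groups <- if (length(cfg$pka))
        data.frame(pka = vapply(cfg$pka, `[[`, numeric(1), "value"),
                   kind = vapply(cfg$pka, `[[`, character(1), "kind"))
    else .emptyGroups()
    sol <- data.frame(
        ph = vapply(cfg$solubility_mg_ml, `[[`, numeric(1), "ph"),
        solubility = vapply(cfg$solubility_mg_ml, `[[`, numeric(1),
                            "value"))
    getd <- function(key, default) if (is.null(cfg[[key]])) default
            else cfg[[key]]
    drugSpec(
        name = cfg$name,
        mw = cfg$molecular_weight_g_mol,
        logP = cfg$logp,
        groups = groups,
        solubility = sol,
        peff = cfg$peff_cm_s,
        particleDiameter = getd("particle_diameter_um", 100),
        particleDensity = getd("particle_density_g_ml", 1.2),
        precipitationTime = getd("precipitation_time_s", 900),
        diffusionCoeff = getd("diffusion_coeff_cm2_s", NA_real_),
        disposition = dispositionParams(
            cl = cfg$clearance_l_h_kg,
            vc = cfg$central_volume_l_kg,
            k12 = getd("k12_1_h", 0), k21 = getd("k21_1_h", 0),
            k13 = getd("k13_1_h", 0), k31 = getd("k31_1_h", 0),
            fpePercent = getd("first_pass_effect_percent", 0),
            bodyWeight = getd("body_weight_kg", 70),
            bloodPlasmaRatio = getd("blood_plasma_ratio", NA_real_),
            fractionUnboundPercent = getd("fraction_unbound_percent",
                                          NA_real_)))
}

#' Write a drug parameter file
#'
#' Inverse of \code{\link{readDrugConfig}}; round-trips a
#' \linkS4class{DrugSpec} through YAML.
#'
#' @param drug a \linkS4class{DrugSpec}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeDrugConfig <- function(drug, path) {
    stopifnot(is(drug, "DrugSpec"))
    d <- drug@disposition
    cfg <- list(
        name = drug@name,
        molecular_weight_g_mol = drug@mw,
        logp = drug@logP,
        pka = lapply(seq_len(nrow(drug@groups)), function(i)
            list(value = drug@groups$pka[i], kind = drug@groups$kind[i])),
        solubility_mg_ml = lapply(seq_len(nrow(drug@solubility)),
            function(i) list(ph = drug@solubility$ph[i],
                             value = drug@solubility$solubility[i])),
        peff_cm_s = drug@peff,
        particle_diameter_um = drug@particleDiameter,
        particle_density_g_ml = drug@particleDensity,
        precipitation_time_s = drug@precipitationTime,
        first_pass_effect_percent = d@fpePercent,
        clearance_l_h_kg = d@cl,
        central_volume_l_kg = d@vc,
        k12_1_h = d@k12, k21_1_h = d@k21, k13_1_h = d@k13, k31_1_h = d@k31,
        body_weight_kg = d@bodyWeight)
    if (is.finite(drug@diffusionCoeff))
        cfg$diffusion_coeff_cm2_s <- drug@diffusionCoeff
    if (is.finite(d@bloodPlasmaRatio))
        cfg$blood_plasma_ratio <- d@bloodPlasmaRatio
    if (is.finite(d@fractionUnboundPercent))
        cfg$fraction_unbound_percent <- d@fractionUnboundPercent
    yaml::write_yaml(cfg, path, precision = 12)
    invisible(path)
}

.fmt <- function(x) signif(x, 6)

#' Write simulation output tables
#'
#' Writes plasma.csv (t_h, conc_ng_mL), gut.csv (per-compartment solid and
#' dissolved masses plus cumulative absorbed), regional.csv and
#' dissolution.csv into a directory, with 6 significant digits and
#' deterministic ordering.
#'
#' @param result a \linkS4class{SimulationResult}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeProfiles <- function(result, dir) {
    stopifnot(is(result, "SimulationResult"))
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    wp <- function(df, file)
        utils::write.csv(df, file.path(dir, file), row.names = FALSE)
    wp(data.frame(t_h = .fmt(result@times),
                  conc_ng_mL = .fmt(result@plasma)), "plasma.csv")
    gut <- data.frame(t_h = .fmt(result@times))
    for (cmp in colnames(result@solid)) {
        gut[[paste0("solid_", cmp)]] <- .fmt(result@solid[, cmp])
        gut[[paste0("dissolved_", cmp)]] <- .fmt(result@dissolved[, cmp])
        gut[[paste0("absorbed_", cmp)]] <- .fmt(result@absorbed[, cmp])
    }
    wp(gut, "gut.csv")
    reg <- regionalAbsorption(result)
    reg$percent_of_dose <- .fmt(reg$percent_of_dose)
    wp(reg, "regional.csv")
    dis <- dissolvedFraction(result, cumulative = TRUE)
    wp(data.frame(t_h = .fmt(dis$t_h),
                  percent_dissolved = .fmt(100 * dis$fraction_dissolved)),
       "dissolution.csv")
    invisible(dir)
}

#' Read a plasma concentration profile CSV
#'
#' @param path CSV with columns \code{t_h} and \code{conc_ng_mL}.
#' @return data.frame(t_h, conc_ng_mL).
#' @export
readPlasmaProfile <- function(path) {
    df <- utils::read.csv(path)
    if (!all(c("t_h", "conc_ng_mL") %in% names(df)))
        stop("profile must have columns t_h and conc_ng_mL: ", path)
    df
}

# Deterministic 31-bit polynomial rolling hash of a character scalar,
# rendered as 8 hex digits; a configuration fingerprint, not cryptographic.
.configHash <- function(x) {
    h <- 0
    for (b in utf8ToInt(x)) h <- (h * 31 + b) %% 2147483647
    sprintf("%08x", h)
}

#' Write a run manifest
#'
#' Records the configuration (and its hash), package version, seed and
#' timestamp of a pipeline run in \code{run_manifest.json}.
#'
#' @param dir output directory.
#' @param config list describing the run inputs.
#' @param seed integer seed used, if any.
#' @return Path of the manifest, invisibly.
#' @export
writeRunManifest <- function(dir, config = list(), seed = NA) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    manifest <- list(
        tool = "bariPBPK",
        version = as.character(utils::packageVersion("bariPBPK")),
        config = config,
        config_hash = .configHash(paste(deparse(config), collapse = "")),
        seed = seed,
        timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
    path <- file.path(dir, "run_manifest.json")
    jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}
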