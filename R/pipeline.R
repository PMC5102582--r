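#' Population estimates from a shift table
#'
#' Derives two-state endpoints per reporter from designated endpoint
#' variants (down from `down_variant`, up from `up_variant`) and
#' estimates pU for every other variant, then aggregates across
#' reporters per variant.
#'
#' @param shifts data.frame in the `shifts` schema (see [tableSchemas()]).
#' @param down_variant,up_variant variant labels providing the limiting
#'   down and up shifts.
#' @param w_c carbon weight of the scaled 2-D space.
#' @return list with `per_reporter` (data.frame variant x reporter) and
#'   `per_variant` (mean, sd, n per variant).
#' @examples
#' tab <- genShiftSeries(noise = NULL)
#' out <- estimatePopulations(tab)
#' out$per_variant
#' @export
estimatePopulations <- function(shifts, down_variant = "wt",
                                up_variant = "ATPgS", w_c = 0.25) {
  key <- paste(shifts$residue, shifts$atom, sep = "|")
  reporters <- unique(key)
  rows <- list()
  for (k in reporters) {
    sub <- shifts[key == k, , drop = FALSE]
    dn <- sub[sub$variant == down_variant, ]
    up <- sub[sub$variant == up_variant, ]
    if (!nrow(dn) || !nrow(up)) next
    ep <- tryCatch(
      twoStateEndpoints(c(h = dn$delta_h_ppm[1], c = dn$delta_c_ppm[1]),
                        c(h = up$delta_h_ppm[1], c = up$delta_c_ppm[1]),
                        w_c = w_c),
      error = function(e) NULL)
    if (is.null(ep)) next
    others <- sub[!(sub$variant %in% c(down_variant, up_variant)), ,
                  drop = FALSE]
    for (i in seq_len(nrow(others))) {
      est <- estimatePU(ep, c(h = others$delta_h_ppm[i],
                              c = others$delta_c_ppm[i]))
      rows[[length(rows) + 1L]] <- data.frame(
        variant = others$variant[i], reporter = k, pU = est$pU,
        deviation_ppm = est$deviation_ppm, flagged = est$flagged,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) stop("no reporter had usable endpoint variants")
  per <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(per, per$variant), function(d) {
    a <- aggregatePU(stats::setNames(
      lapply(seq_len(nrow(d)), function(i)
        list(pU = d$pU[i], deviation_ppm = d$deviation_ppm[i],
             flagged = d$flagged[i])), d$reporter))
    data.frame(variant = d$variant[1], pU_mean = a$mean, pU_sd = a$sd,
               n = a$n, stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  list(per_reporter = per, per_variant = agg)
}

#' Tumbling times from a table of buildup curves
#'
#' Fits each reporter's buildup curve, converts eta to
#' \eqn{S^2_{axis}\tau_c}, and (when reference order parameters are
#' supplied) estimates the shared domain tumbling time with
#' [globalTau()].
#'
#' @param buildup data.frame in the `buildup` schema.
#' @param s2_table optional data.frame with `reporter` and `s2_axis`
#'   reference order parameters (e.g. measured on the isolated domain
#'   and temperature-extrapolated with [extrapolateS2()]).
#' @return list with `fits` (per-reporter eta, delta, s2tau_ns) and,
#'   with `s2_table`, `global` (from [globalTau()]).
#' @export
fitBuildupTable <- function(buildup, s2_table = NULL) {
  fits <- do.call(rbind, lapply(split(buildup, buildup$reporter),
    function(d) {
      d <- d[order(d$delay_s), ]
      f <- fitBuildup(d$delay_s, d$ratio, d$sigma)
      data.frame(reporter = d$reporter[1], eta = f@eta,
                 delta_density = f@deltaDensity,
                 eta_se = sqrt(max(f@cov[1, 1], 0)),
                 s2tau_ns = s2TauFromEta(f@eta),
                 stringsAsFactors = FALSE)
    }))
  rownames(fits) <- NULL
  out <- list(fits = fits)
  if (!is.null(s2_table)) {
    m <- merge(fits, s2_table, by = "reporter")
    out$global <- globalTau(m$s2_axis, m$s2tau_ns)
  }
  out
}

#' Run the analysis pipeline from a configuration list
#'
#' Orchestrates the stages on file-based inputs and returns a single
#' machine-readable report.  Stages: `"simulate"` (write synthetic
#' fixture CSVs into `out_dir`), `"pops"` (population estimation from a
#' shift table), `"tqfit"` (buildup fitting and global tumbling time),
#' `"n15fit"` (model-free analysis) and `"bind"` (titration Kd fit).
#' Identical config and seed give an identical report payload.
#'
#' @param config list with elements `stages` (character vector), `seed`
#'   (integer, used by `"simulate"`), `out_dir`, and per-stage input
#'   paths `shifts`, `buildup`, `relax15n`, `titration`, optional
#'   `s2_table` (data.frame) and `options` (named list of overrides:
#'   `w_c`, `noise`).
#' @param report_path optional path; when given the report is written as
#'   JSON.
#' @return report list, invisibly when `report_path` is set.
#' @export
runPipeline <- function(config, report_path = NULL) {
  if (is.null(config$stages) || !length(config$stages))
    stop("config must name at least one stage")
  known <- c("simulate", "pops", "tqfit", "n15fit", "bind")
  bad <- setdiff(config$stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  out_dir <- config$out_dir %||% tempdir()
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  opts <- config$options %||% list()
  report <- list(package_version =
                   as.character(utils::packageVersion("p97nmr")),
                 seed = config$seed, stages = config$stages,
                 options = opts, warnings = character())
  for (stage in config$stages) {
    report[[stage]] <- switch(stage,
      simulate = {
        noise <- if (isTRUE(opts$noise_free)) NULL else
          opts$noise %||% defaultNoise()
        shifts <- genShiftSeries(noise = noise, seed = config$seed)
        writeTable(shifts, file.path(out_dir, "shifts.csv"))
        ttr <- genTitration(schemeScenario()$wt, noise = noise,
                            seed = config$seed)
        writeTable(ttr, file.path(out_dir, "titration.csv"))
        list(files = c("shifts.csv", "titration.csv"), dir = out_dir)
      },
      pops = {
        path <- config$shifts %||% file.path(out_dir, "shifts.csv")
        res <- estimatePopulations(readTable(path, "shifts"),
                                   w_c = opts$w_c %||% 0.25)
        res$per_variant
      },
      tqfit = {
        path <- config$buildup %||% file.path(out_dir, "buildup.csv")
        res <- fitBuildupTable(readTable(path, "buildup"),
                               s2_table = config$s2_table)
        c(list(fits = res$fits),
          if (!is.null(res$global))
            list(tau_c_ns = res$global$tau_c_ns,
                 tau_se_ns = res$global$se_ns))
      },
      n15fit = {
        path <- config$relax15n %||% file.path(out_dir, "relax15n.csv")
        res <- modelFreeFit(readTable(path, "relax15n"))
        c(list(fits = res$fits),
          if (!is.null(res$summary))
            list(tau_c_mean_ns = res$summary@mean,
                 tau_c_sd_ns = res$summary@sd))
      },
      bind = {
        path <- config$titration %||% file.path(out_dir, "titration.csv")
        d <- readTable(path, "titration")
        fit <- fitTitration(titrationSeries(d, PT = d$protein_total_uM[1]))
        list(kd_macro_uM = fit@kd, kd_se_uM = fit@se, deltaB = fit@deltaB)
      })
  }
  if (!is.null(report_path)) {
    jsonlite::write_json(report, report_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, force = TRUE)
    return(invisible(report))
  }
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a
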