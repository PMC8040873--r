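#' Run a multi-stage stabilization study from a config file
#'
#' Orchestrates any subset of the analysis stages from a single JSON
#' config and collects the typed results into one report with
#' provenance. All referenced inputs are validated before any stage
#' runs, so a malformed config never produces partial output.
#'
#' Config sections (all optional, each a JSON object):
#' \describe{
#'   \item{decay}{`reference`, `treated`: decay CSV paths
#'     (`time_min,activity`).}
#'   \item{michaelis}{`file`: kinetics CSV (`substrate_mM,rate_per_min`).}
#'   \item{titration}{`file`: titration CSV (`ligand_total_M,signal`);
#'     `protein_total`; optional `alpha` (default 0.05), `gamma`
#'     (default 1), `nu_range` (default [0.4, 0.9]), `n_classes`
#'     (default 0 = skip the full-model fit).}
#'   \item{dsc}{`file`: thermogram CSV; optional `scan_rate`, `T_ref`
#'     (default 298.15), `rate_unit` (default "per_second").}
#'   \item{motif}{`structure`: PDB/mmCIF to search; `query_structure`
#'     and `query_residues` (e.g. `["A:326","A:389","A:392","A:393"]`);
#'     optional `cutoff` (2.5), `handedness` ("both"), `annotate`
#'     (logical).}
#' }
#'
#' @param config Path to a JSON config file, or an equivalent named
#'   list.
#' @param report_path Optional path; when given, the report is written
#'   there as JSON (full double precision).
#' @return Object of class `study_report`: named list of per-stage
#'   results plus `provenance` (inputs, package version, timestamp).
#' @export
run_study <- function(config, report_path = NULL) {
  cfg <- if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    jsonlite::read_json(config, simplifyVector = TRUE)
  } else config
  if (!is.list(cfg)) stop("malformed config: expected a JSON object")

  ## validate every referenced input before running anything
  inputs <- character(0)
  need <- function(section, field) {
    val <- cfg[[section]][[field]]
    if (is.null(val)) stop("config section '", section,
                           "' is missing required field '", field, "'")
    val
  }
  for (sec_field in list(c("decay", "reference"), c("decay", "treated"),
                         c("michaelis", "file"), c("titration", "file"),
                         c("dsc", "file"), c("motif", "structure"),
                         c("motif", "query_structure"))) {
    if (!is.null(cfg[[sec_field[1L]]])) {
      p <- need(sec_field[1L], sec_field[2L])
      if (!file.exists(p)) stop("input file not found: ", p)
      inputs <- c(inputs, p)
    }
  }

  report <- list()

  if (!is.null(cfg$decay)) {
    ref <- fit_exponential_decay(read_decay_csv(cfg$decay$reference,
                                                label = "reference"))
    trt <- fit_exponential_decay(read_decay_csv(cfg$decay$treated,
                                                label = "treated"))
    report$decay <- list(
      reference = unclass(ref), treated = unclass(trt),
      fold_stabilization = fold_stabilization(ref, trt))
  }

  if (!is.null(cfg$michaelis)) {
    df <- read_mm_csv(cfg$michaelis$file)
    report$michaelis <- unclass(
      fit_michaelis_menten(df$substrate_mM, df$rate_per_min))
  }

  if (!is.null(cfg$titration)) {
    tc <- cfg$titration
    series <- read_titration_csv(tc$file, protein_total = need("titration", "protein_total"),
                                 alpha = tc$alpha %||% 0.05,
                                 gamma = tc$gamma %||% 1)
    bound <- bound_from_signal(series)
    pts <- scatchard_points(bound)
    seg <- fit_scatchard_segment(pts, nu_range = unlist(tc$nu_range %||% c(0.4, 0.9)))
    report$titration <- list(scatchard_segment = unclass(seg),
                             points = pts)
    ncl <- tc$n_classes %||% 0L
    if (ncl >= 1L) {
      model <- fit_multisite(bound$c_free, bound$nu, n_classes = ncl)
      report$titration$multisite <- list(classes = model$classes,
                                         sse = attr(model, "sse"))
    }
  }

  if (!is.null(cfg$dsc)) {
    tg <- read_thermogram_csv(cfg$dsc$file, scan_rate = cfg$dsc$scan_rate)
    fit <- fit_thermogram(tg)
    ey <- eyring_parameters(fit$params,
                            T_ref = cfg$dsc$T_ref %||% 298.15,
                            rate_unit = cfg$dsc$rate_unit %||% "per_second")
    report$dsc <- list(arrhenius = unclass(fit$params),
                       fit_quality_r = fit$quality,
                       eyring = unclass(ey))
  }

  if (!is.null(cfg$motif)) {
    mc <- cfg$motif
    qs <- parse_structure(mc$query_structure)
    qres <- .parse_residue_list(unlist(need("motif", "query_residues")))
    query <- motif_query(suppressWarnings(sidechain_vectors(qs, qres)),
                         source = mc$query_structure)
    target <- parse_structure(mc$structure)
    hits <- search_motif(target, query,
                         rmsd_cutoff = mc$cutoff %||% 2.5,
                         handedness = mc$handedness %||% "both")
    report$motif <- list(hits = as.data.frame(hits))
    if (isTRUE(mc$annotate) && length(hits)) {
      occ <- annotate_pocket(target, hits[[1L]])
      report$motif$pocket <- list(classification = occ$classification,
                                  water_count = occ$water_count,
                                  ions = occ$ions)
    }
  }

  if (!length(report))
    stop("config names no known stage (decay, michaelis, titration, dsc, motif)")

  report$provenance <- list(
    inputs = inputs,
    package = "ion4d",
    version = as.character(utils::packageVersion("ion4d")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE))
  class(report) <- "study_report"
  if (!is.null(report_path)) {
    jsonlite::write_json(unclass(report), report_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, force = TRUE)
  }
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.study_report <- function(x, ...) {
  stages <- setdiff(names(x), "provenance")
  cat("Study report (stages: ", paste(stages, collapse = ", "), ")\n", sep = "")
  if (!is.null(x$decay))
    cat(sprintf("  decay: fold stabilization = %.4g\n",
                x$decay$fold_stabilization))
  if (!is.null(x$michaelis))
    cat(sprintf("  michaelis: Km = %.4g mM, kcat = %.4g min^-1\n",
                x$michaelis$Km, x$michaelis$kcat))
  if (!is.null(x$titration))
    cat(sprintf("  titration: segment n = %.4g, K = %.4g M^-1\n",
                x$titration$scatchard_segment$n,
                x$titration$scatchard_segment$K))
  if (!is.null(x$dsc))
    cat(sprintf("  dsc: E_A = %.4g kcal/mol, T* = %.4g K, dG_act = %.4g kcal/mol\n",
                x$dsc$arrhenius$E_A, x$dsc$arrhenius$T_star,
                x$dsc$eyring$dG_act))
  if (!is.null(x$motif))
    cat(sprintf("  motif: %d hit(s)\n", nrow(x$motif$hits)))
  invisible(x)
}

#' Compare computed report values against expected values
#'
#' Tabulates computed quantities against user-supplied expectations
#' (e.g. published table entries) with absolute and relative deltas.
#' Keys present on only one side are reported as missing rather than
#' silently dropped.
#'
#' @param computed Named numeric vector (or a flat named list) of
#'   computed values; a `study_report` is flattened automatically.
#' @param expected Named numeric vector of expected values; may be
#'   empty, in which case the table lists computed values only.
#' @return data.frame with columns `key`, `computed`, `expected`,
#'   `abs_delta`, `rel_delta`, `status` (`"ok"`, `"missing_expected"`,
#'   `"missing_computed"`).
#' @export
table_check <- function(computed, expected = numeric(0)) {
  if (inherits(computed, "study_report")) {
    flat <- unlist(unclass(computed)[setdiff(names(computed), "provenance")])
    computed <- flat[vapply(flat, function(v)
      is.numeric(v) || !is.na(suppressWarnings(as.numeric(v))), logical(1L))]
    computed <- stats::setNames(as.numeric(computed), names(computed))
  }
  computed <- unlist(computed)
  expected <- unlist(expected)
  keys <- union(names(computed), names(expected))
  comp <- computed[keys]; expv <- expected[keys]
  status <- ifelse(is.na(comp), "missing_computed",
                   ifelse(is.na(expv),
                          if (length(expected)) "missing_expected" else "ok",
                          "ok"))
  data.frame(key = keys,
             computed = unname(comp),
             expected = unname(expv),
             abs_delta = unname(abs(comp - expv)),
             rel_delta = unname(abs(comp - expv) / abs(expv)),
             status = status,
             row.names = NULL)
}
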