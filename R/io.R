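#' CSV schemas used by the pipeline
#'
#' Column contracts for the four tabular inputs.  Units are encoded in
#' the column-name suffixes (`_ppm`, `_uM`, `_s`); rates are s^-1.
#'
#' @return named list: required and optional column names per schema id.
#' @export
tableSchemas <- function() {
  list(
    shifts = list(
      required = c("variant", "state", "residue", "atom", "delta_h_ppm",
                   "delta_c_ppm"),
      optional = c("sigma_h_ppm", "sigma_c_ppm"),
      key = c("variant", "state", "residue", "atom")),
    buildup = list(
      required = c("reporter", "delay_s", "ratio", "sigma"),
      optional = c("residue", "atom"),
      key = c("reporter", "delay_s")),
    relax15n = list(
      required = c("residue", "r1", "r1rho", "noe", "field_h_mhz",
                   "nu1_hz", "offset_hz"),
      optional = c("r1_err", "r1rho_err", "noe_err"),
      key = "residue"),
    titration = list(
      required = c("reporter", "protein_total_uM", "ligand_total_uM",
                   "delta_h_ppm", "delta_c_ppm"),
      optional = c("residue", "atom", "sigma_ppm", "sigma_h_ppm",
                   "sigma_c_ppm"),
      key = c("reporter", "ligand_total_uM"))
  )
}

#' Read and validate a pipeline CSV
#'
#' @param path file path.
#' @param schema one of `"shifts"`, `"buildup"`, `"relax15n"`,
#'   `"titration"`.
#' @return validated data.frame; parse errors name the offending column
#'   or row.
#' @export
readTable <- function(path, schema = names(tableSchemas())) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("file not found: ", path)
  sc <- tableSchemas()[[schema]]
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(sc$required, names(d))
  if (length(miss))
    stop("schema '", schema, "': missing column(s) ",
         paste(miss, collapse = ", "), " in ", path)
  num <- grep("_(ppm|uM|s|hz|mhz)$|^(r1|r1rho|noe|ratio|sigma|residue)",
              names(d), value = TRUE, ignore.case = TRUE)
  for (cl in intersect(num, names(d))) {
    if (!is.numeric(d[[cl]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(d[[cl]]))) &
                   !is.na(d[[cl]]))
      if (length(bad))
        stop("schema '", schema, "': non-numeric value in column '", cl,
             "', row ", bad[1])
      d[[cl]] <- as.numeric(d[[cl]])
    }
  }
  keys <- do.call(paste, c(d[sc$key], sep = "|"))
  if (anyDuplicated(keys))
    stop("schema '", schema, "': duplicate key at row ",
         which(duplicated(keys))[1], " (",
         keys[which(duplicated(keys))[1]], ")")
  d
}

#' Write a pipeline CSV at full precision
#'
#' @param table data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTable <- function(table, path) {
  utils::write.csv(format(table, digits = 15, trim = TRUE,
                          scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a binding-scheme configuration (YAML or JSON)
#'
#' Expected structure: one entry per class label, each with keys `K1`,
#' `K2_uM`, `gamma`, `K5`, `PT_uM`, `LT_uM`.  Unknown keys are rejected.
#'
#' @param path file path (`.yaml`, `.yml` or `.json`).
#' @return list per class: `params` (a [SchemeOneParams-class]) and
#'   `totals` (from [mixtureTotals()]).
#' @export
readSchemeConfig <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  allowed <- c("K1", "K2_uM", "gamma", "K5", "PT_uM", "LT_uM")
  lapply(raw, function(cls) {
    unknown <- setdiff(names(cls), allowed)
    if (length(unknown))
      stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    miss <- setdiff(allowed, names(cls))
    if (length(miss))
      stop("missing config key(s): ", paste(miss, collapse = ", "))
    list(params = deriveScheme(cls$K1, cls$K2_uM, cls$gamma, cls$K5),
         totals = mixtureTotals(cls$PT_uM, cls$LT_uM))
  })
}
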