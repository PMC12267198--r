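#' Read a model configuration file
#'
#' Loads a complete parameter bundle from the package's JSON configuration
#' format (the format written by [write_model_config()]), applies defaults
#' for omitted optional settings, and validates every invariant.  A missing
#' required section raises a load error naming the section; an invariant
#' violation raises a validation error naming the field and rule.
#'
#' Numbers are stored at full double precision (17 significant digits), so a
#' write/read round trip reproduces the bundle exactly.
#'
#' @param path Path to a configuration file.
#' @return A validated `pdl1_params` bundle.
#' @export
read_model_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = TRUE)
  required <- c("population", "uptake", "traditional_shares", "transitions",
                "mixes", "utilities", "age_adjustment", "ae_profiles",
                "life_table", "demographics")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop("config load error: missing required section(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  comps <- lapply(raw[required], tibble::as_tibble)
  # columns that are all-NA serialize as logical; restore their types
  comps$transitions <- fix_na_cols(comps$transitions,
                                   c(treatment = "character", p2 = "numeric",
                                     p3 = "numeric", hr_lower = "numeric",
                                     hr_upper = "numeric"))
  do.call(model_params,
          c(list(settings = raw$settings %||% list()), comps))
}

fix_na_cols <- function(df, types) {
  for (nm in names(types)) {
    if (nm %in% names(df) && is.logical(df[[nm]])) {
      df[[nm]] <- if (types[[nm]] == "character") as.character(df[[nm]])
                  else as.numeric(df[[nm]])
    }
  }
  df
}

#' Write a model configuration file
#'
#' Serializes a `pdl1_params` bundle to JSON at full double precision.  The
#' result can be read back with [read_model_config()] to reproduce the
#' bundle exactly.
#'
#' @param params A validated `pdl1_params` bundle.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model_config <- function(params, path) {
  stopifnot(inherits(params, "pdl1_params"))
  out <- unclass(params)
  jsonlite::write_json(out, path, digits = I(17), auto_unbox = TRUE,
                       dataframe = "rows", pretty = TRUE, na = "null")
  invisible(path)
}
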