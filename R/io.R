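# Readers and writers for the pipeline's CSV/SMILES/JSON interchange
# formats. CSV dialect: comma-separated, UTF-8, header row required, "."
# decimal. Output tables carry a commented metadata header (tool version,
# seed, config hash) so runs are traceable; readers skip "#" lines.

.ASSAY_COLS <- c("compound_id", "conc_uM", "a405_t0_sample", "a405_t20_sample",
                 "a405_t0_blank", "a405_t20_blank", "replicate")
.KINETIC_COLS <- c("s_mM", "i_mM", "v0")
.COMPOUND_COLS <- c("compound_id", "smiles", "pic50")

.read_csv <- function(path, required, what) {
  if (!file.exists(path)) stop(what, " file not found: ", path, call. = FALSE)
  df <- tryCatch(
    utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE),
    error = function(e) stop("malformed ", what, " CSV (", path, "): ",
                             conditionMessage(e), call. = FALSE))
  check_columns(df, required, paste(what, "CSV"))
  num_cols <- setdiff(required, c("compound_id", "smiles"))
  for (cl in num_cols) {
    v <- suppressWarnings(as.numeric(df[[cl]]))
    bad <- which(is.na(v) & !is.na(df[[cl]]) & df[[cl]] != "")
    if (length(bad) > 0) {
      stop(what, " CSV: non-numeric value in column '", cl, "' at data line ",
           bad[1], call. = FALSE)
    }
    df[[cl]] <- v
  }
  df
}

#' Read an assay absorbance table
#'
#' Expected columns: `compound_id`, `conc_uM`, `a405_t0_sample`,
#' `a405_t20_sample`, `a405_t0_blank`, `a405_t20_blank`, `replicate`.
#'
#' @param path CSV file path.
#' @return data.frame.
#' @export
read_assay_csv <- function(path) .read_csv(path, .ASSAY_COLS, "assay")

#' Read an initial-velocity kinetics table
#'
#' Expected columns: `s_mM`, `i_mM`, `v0`; optional `sd`, `replicate`.
#'
#' @param path CSV file path.
#' @return a [kinetic_dataset()].
#' @export
read_kinetics_csv <- function(path) {
  df <- .read_csv(path, .KINETIC_COLS, "kinetics")
  out <- data.frame(s = df$s_mM, i = df$i_mM, v0 = df$v0)
  if (!is.null(df$sd)) out$sd <- as.numeric(df$sd)
  if (!is.null(df$replicate)) out$replicate <- df$replicate
  kinetic_dataset(out)
}

#' Read a compound table
#'
#' Expected columns: `compound_id`, `smiles`, `pic50`; extra columns are
#' kept.
#'
#' @param path CSV file path.
#' @return data.frame.
#' @export
read_compounds_csv <- function(path) .read_csv(path, .COMPOUND_COLS, "compound")

#' Read a SMILES file
#'
#' One record per line: `SMILES<TAB>id` or bare SMILES (ids are then
#' `cmpd_1`, `cmpd_2`, ...). Blank lines and `#` comments are skipped.
#'
#' @param path file path.
#' @return data.frame with `compound_id`, `smiles`.
#' @export
read_smiles_file <- function(path) {
  if (!file.exists(path)) stop("SMILES file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t")
  smiles <- vapply(parts, `[[`, character(1), 1)
  ids <- vapply(seq_along(parts), function(k) {
    if (length(parts[[k]]) >= 2) parts[[k]][[2]] else sprintf("cmpd_%d", k)
  }, character(1))
  data.frame(compound_id = ids, smiles = smiles, stringsAsFactors = FALSE)
}

#' Write a SMILES file
#'
#' @param records data.frame with `compound_id` and `smiles`.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_smiles_file <- function(records, path) {
  check_columns(records, c("compound_id", "smiles"), "compound table")
  writeLines(paste(records$smiles, records$compound_id, sep = "\t"), path)
  invisible(path)
}

# Commented metadata header for traceable outputs.
.meta_header <- function(seed = NULL, config = NULL) {
  ver <- as.character(utils::packageVersion("inhibscreen"))
  h <- c(sprintf("# tool=inhibscreen version=%s", ver))
  if (!is.null(seed)) h <- c(h, sprintf("# seed=%s", format(seed)))
  if (!is.null(config)) {
    cfg <- jsonlite::toJSON(config, auto_unbox = TRUE)
    h <- c(h, sprintf("# config_sha=%s", substr(.simple_hash(cfg), 1, 12)),
           sprintf("# config=%s", cfg))
  }
  h
}

# Small polynomial rolling hash, enough to tag outputs with their
# configuration.
.simple_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "")))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Write a table with a metadata header
#'
#' @param df data.frame.
#' @param path output path.
#' @param seed,config optional metadata echoed into the commented header.
#' @return invisibly, the path.
#' @export
write_table_csv <- function(df, path, seed = NULL, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.meta_header(seed, config), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}
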