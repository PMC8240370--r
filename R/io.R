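# Readers and writers. All tabular inputs are delimited text (tab, comma or
# semicolon; auto-detected) with probes in rows and samples in columns, the
# layout of GEO series-matrix style exports. Readers reject structural
# corruption (duplicate IDs, ragged rows) instead of repairing it silently.

MODEL_SCHEMA_VERSION <- 1L

.detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  counts <- c("\t" = lengths(regmatches(header, gregexpr("\t", header))),
              "," = lengths(regmatches(header, gregexpr(",", header))),
              ";" = lengths(regmatches(header, gregexpr(";", header))))
  if (all(counts == 0L)) stop("could not detect a delimiter in ", path)
  names(counts)[which.max(counts)]
}

.read_table_matrix <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) sep <- .detect_sep(path)
  dt <- data.table::fread(path, sep = sep, header = TRUE,
                          na.strings = c("NA", "N/A", "null", "NULL", ""),
                          data.table = FALSE, colClasses = "character")
  if (nrow(dt) == 0L) stop("empty table: ", path)
  ids <- dt[[1L]]
  .check_ids(ids, "probe")
  .check_ids(colnames(dt)[-1L], "sample")
  m <- suppressWarnings(
    vapply(dt[-1L], function(col) as.numeric(col), numeric(nrow(dt))))
  if (nrow(dt) == 1L) m <- matrix(m, nrow = 1L, dimnames = list(NULL, colnames(dt)[-1L]))
  rownames(m) <- ids
  m
}

#' Read methylated/unmethylated signal intensities
#'
#' Two dialects are supported. `"paired"`: a single table whose header pairs
#' columns per sample, e.g. `S1 Methylated` / `S1 Unmethylated` (separator
#' may be a space, `.` or `_`; case-insensitive). `"split"`: two tables with
#' identical probe sets, one of methylated and one of unmethylated signals,
#' aligned by probe ID (never by row order). Non-numeric cells become
#' missing values.
#'
#' @param path Path to the intensity table (paired dialect) or the
#'   methylated table (split dialect).
#' @param unmethylated Path to the unmethylated table; supplying it selects
#'   the split dialect.
#' @param sep Field delimiter; `NULL` (default) auto-detects among tab,
#'   comma and semicolon.
#' @return A list with numeric matrices `methylated` and `unmethylated`
#'   (probes x samples, `NA` = missing).
#' @export
read_intensity_table <- function(path, unmethylated = NULL, sep = NULL) {
  if (!is.null(unmethylated)) {
    m <- .read_table_matrix(path, sep)
    u <- .read_table_matrix(unmethylated, sep)
    if (!setequal(rownames(m), rownames(u)))
      stop("methylated and unmethylated files cover different probes")
    u <- u[rownames(m), , drop = FALSE]
    if (!identical(colnames(m), colnames(u)))
      stop("methylated and unmethylated files cover different samples")
  } else {
    raw <- .read_table_matrix(path, sep)
    cn <- colnames(raw)
    pat <- "[ ._](?i:methylated)$"
    upat <- "[ ._](?i:unmethylated)$"
    is_u <- grepl(upat, cn, perl = TRUE)
    is_m <- grepl(pat, cn, perl = TRUE) & !is_u
    samples_m <- sub(pat, "", cn[is_m], perl = TRUE)
    samples_u <- sub(upat, "", cn[is_u], perl = TRUE)
    orphans <- c(setdiff(samples_m, samples_u), setdiff(samples_u, samples_m),
                 cn[!is_m & !is_u])
    if (length(orphans) > 0L)
      stop("unpaired or unrecognized intensity columns: ",
           paste(orphans, collapse = ", "))
    m <- raw[, which(is_m)[match(samples_m, samples_m)], drop = FALSE]
    u <- raw[, which(is_u)[match(samples_m, samples_u)], drop = FALSE]
    colnames(m) <- samples_m
    colnames(u) <- samples_m
  }
  intensity_matrix(m, u)
  list(methylated = m, unmethylated = u)
}

#' Read a beta-value matrix
#'
#' Delimited text, probes in rows, samples in columns. Values outside
#' `[0, 1]` by more than `tol` raise an error naming the offending probe and
#' sample (the usual cause is feeding M-values or raw intensities); values
#' within `tol` of the bounds are clamped with a warning.
#'
#' @param path Path to the table.
#' @param sep Field delimiter; `NULL` auto-detects.
#' @param tol Bound tolerance for clamping; default 1e-6.
#' @return Numeric beta matrix (`NA` = missing).
#' @export
read_beta_matrix <- function(path, sep = NULL, tol = 1e-6) {
  m <- .read_table_matrix(path, sep)
  over <- which(!is.na(m) & (m < -tol | m > 1 + tol), arr.ind = TRUE)
  if (nrow(over) > 0L)
    stop(sprintf(
      "value %g at probe '%s', sample '%s' is not a beta value (outside [0, 1])",
      m[over[1L, 1L], over[1L, 2L]], rownames(m)[over[1L, 1L]],
      colnames(m)[over[1L, 2L]]))
  clamp <- !is.na(m) & (m < 0 | m > 1)
  if (any(clamp)) {
    warning(sum(clamp), " value(s) within ", tol,
            " of the [0, 1] bounds were clamped")
    m[clamp & m < 0] <- 0
    m[clamp & m > 1] <- 1
  }
  validate_beta(m)
  m
}

#' Read a probe annotation table
#'
#' Expects at least two columns: probe IDs and chromosome labels (header
#' names are free; the first column is taken as the probe ID and a column
#' named like "chr"/"chromosome" — or else the second column — as the
#' label). Labels are normalized via [normalize_chromosome()].
#'
#' @param path Path to the table.
#' @param sep Field delimiter; `NULL` auto-detects.
#' @return A [probe_annotation()] data.frame.
#' @export
read_probe_annotation <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) sep <- .detect_sep(path)
  dt <- data.table::fread(path, sep = sep, header = TRUE, data.table = FALSE,
                          colClasses = "character")
  chr_col <- grep("^(chr|chrom|chromosome)$", tolower(names(dt)))
  chr_col <- if (length(chr_col) > 0L) chr_col[1L] else 2L
  probe_annotation(dt[[1L]], dt[[chr_col]])
}

#' Read a sample sheet
#'
#' Expects a column of sample IDs (first column, or one named like
#' "sample"/"sample_id") and optionally a sex column (named like
#' "sex"/"gender"); sex labels are normalized via [normalize_sex()].
#'
#' @param path Path to the table.
#' @param sep Field delimiter; `NULL` auto-detects.
#' @return A [sample_sheet()] data.frame.
#' @export
read_sample_sheet <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) sep <- .detect_sep(path)
  dt <- data.table::fread(path, sep = sep, header = TRUE, data.table = FALSE,
                          colClasses = "character")
  id_col <- grep("^(sample|sample_id|sampleid|id)$", tolower(names(dt)))
  id_col <- if (length(id_col) > 0L) id_col[1L] else 1L
  sex_col <- grep("^(sex|gender)$", tolower(names(dt)))
  sex <- if (length(sex_col) > 0L) dt[[sex_col[1L]]] else NULL
  sample_sheet(dt[[id_col]], sex)
}

# Full-precision decimal encoding: 17 significant digits round-trip IEEE
# doubles exactly through as.numeric().
.fmt <- function(x) sprintf("%.17g", x)

#' Write a trained model to structured text
#'
#' The model file is human-readable, versioned and self-contained:
#' prediction needs nothing besides a beta matrix and this file. Layout: a
#' `key: value` metadata block, then one `[axis X]` / `[axis Y]` block each
#' holding tab-separated per-probe records `probe_id  center  loading`.
#' Floating-point values are printed with 17 significant digits so
#' [read_model()] reproduces the model exactly.
#'
#' @param model A validated `sex_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  validate_model(model)
  md <- model$metadata
  lines <- c(
    "# methylSex trained sex classifier",
    paste0("schema_version: ", MODEL_SCHEMA_VERSION),
    paste0("package_version: ", md$package_version %||% "unknown"),
    paste0("n_female: ", md$n_female), paste0("n_male: ", md$n_male),
    paste0("p_threshold: ", .fmt(md$p_threshold)),
    paste0("delta_threshold: ", .fmt(md$delta_threshold)),
    paste0("seed: ", md$seed),
    paste0("sd_method: ", md$sd_method %||% "population"),
    paste0("x_orientation_sign: ", model$x_sign),
    paste0("y_orientation_sign: ", model$y_sign),
    paste0("x_variance_explained: ", .fmt(md$x_variance_explained)),
    paste0("y_variance_explained: ", .fmt(md$y_variance_explained)),
    paste0("x_separation: ", .fmt(md$x_separation)),
    paste0("y_separation: ", .fmt(md$y_separation)),
    "[axis X]",
    paste(model$x_probes, .fmt(model$x_center), .fmt(model$x_loadings),
          sep = "\t"),
    "[axis Y]",
    paste(model$y_probes, .fmt(model$y_center), .fmt(model$y_loadings),
          sep = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a trained model
#'
#' Parses the structured text written by [write_model()], checks the schema
#' version and re-validates all model invariants (unit-norm loadings,
#' disjoint probe sets) so a hand-edited file cannot sneak in an invalid
#' classifier.
#'
#' @param path Path to the model file.
#' @return A `sex_model`.
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  ax_x <- which(lines == "[axis X]")
  ax_y <- which(lines == "[axis Y]")
  if (length(ax_x) != 1L || length(ax_y) != 1L || ax_y < ax_x)
    stop("model incomplete: expected one [axis X] and one [axis Y] block")
  meta_lines <- lines[seq_len(ax_x - 1L)]
  kv <- strsplit(meta_lines, ": ", fixed = TRUE)
  meta <- setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  if (is.na(meta["schema_version"]))
    stop("model file lacks a schema_version field")
  ver <- as.integer(meta[["schema_version"]])
  if (ver != MODEL_SCHEMA_VERSION)
    stop(sprintf("model schema version %d does not match supported version %d",
                 ver, MODEL_SCHEMA_VERSION))
  parse_axis <- function(rows, axis) {
    if (length(rows) == 0L) stop("model incomplete: empty axis ", axis, " block")
    parts <- strsplit(rows, "\t", fixed = TRUE)
    if (any(lengths(parts) != 3L))
      stop("malformed per-probe record in axis ", axis, " block")
    list(probes = vapply(parts, `[`, "", 1L),
         center = as.numeric(vapply(parts, `[`, "", 2L)),
         loadings = as.numeric(vapply(parts, `[`, "", 3L)))
  }
  x <- parse_axis(lines[(ax_x + 1L):(ax_y - 1L)], "X")
  y <- parse_axis(lines[(ax_y + 1L):length(lines)], "Y")
  num <- function(k) if (is.na(meta[k])) NULL else as.numeric(meta[[k]])
  model <- structure(list(
    x_probes = x$probes, y_probes = y$probes,
    x_center = x$center, y_center = y$center,
    x_loadings = x$loadings, y_loadings = y$loadings,
    x_sign = as.numeric(meta[["x_orientation_sign"]]),
    y_sign = as.numeric(meta[["y_orientation_sign"]]),
    metadata = list(
      schema_version = ver,
      package_version = unname(meta["package_version"]),
      n_female = as.integer(num("n_female")), n_male = as.integer(num("n_male")),
      p_threshold = num("p_threshold"),
      delta_threshold = num("delta_threshold"),
      seed = as.integer(num("seed")),
      sd_method = unname(meta["sd_method"]),
      n_selected_x = length(x$probes), n_selected_y = length(y$probes),
      x_variance_explained = num("x_variance_explained"),
      y_variance_explained = num("y_variance_explained"),
      x_separation = num("x_separation"), y_separation = num("y_separation")
    )
  ), class = "sex_model")
  validate_model(model)
  model
}

#' Write predictions to CSV
#'
#' One row per sample: sample ID, both axis scores (8 significant digits),
#' karyotype call, predicted sex, labelled sex, mismatch flag and
#' near-boundary flag. Unlabelled samples get empty label fields. Output is
#' deterministic: identical predictions produce byte-identical files.
#'
#' @param predictions Data frame from [estimate_sex()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  out <- predictions
  out$x_score <- sprintf("%.8g", out$x_score)
  out$y_score <- sprintf("%.8g", out$y_score)
  for (col in c("labelled_sex", "label_mismatch", "near_boundary"))
    if (col %in% names(out)) {
      v <- as.character(out[[col]])
      v[is.na(v)] <- ""
      out[[col]] <- v
    }
  # karyotype calls contain commas ("46,XX"), so fields are quoted
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write a beta matrix (or any probe x sample matrix) as TSV
#'
#' @param m Numeric matrix with probe rownames and sample colnames.
#' @param path Output path.
#' @param id_col Header name of the probe-ID column.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path, id_col = "probe_id") {
  dt <- data.table::data.table(probe = rownames(m))
  data.table::setnames(dt, "probe", id_col)
  for (j in seq_len(ncol(m))) dt[[colnames(m)[j]]] <- m[, j]
  data.table::fwrite(dt, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}
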