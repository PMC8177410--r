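#' The donor-recipient covariate schema
#'
#' Builds the 36-covariate encoding schema used throughout the package: the
#' donor and recipient characteristics recorded for each lung transplant,
#' with every categorical variable expanded into one-of-k binary dummies
#' (one indicator per category, no reference category dropped).
#'
#' The 36 covariates are tagged `x1` ... `x36`:
#' \itemize{
#'   \item binary: `x1` (recipient sex), `x11` (donor sex), `x29`
#'     (cardiopulmonary bypass), `x30` (pulmonary tailoring);
#'   \item dummy groups: recipient pathology `desease2` (`x3`-`x7`),
#'     pre-transplant status `pre_tx` (`x8`-`x10`), donor cause of death
#'     `death_d` (`x13`-`x17`), transplant type `type_tx` (`x20`-`x24`),
#'     cold ischemia time class `cold_isch` (`x25`-`x28`);
#'   \item continuous: recipient/donor age (`x2`, `x12`), days of
#'     endotracheal intubation (`x18`), donor oxygenation index PaO2/FiO2
#'     (`x19`), pre-transplant PO2/PCO2 (`x31`, `x32`), and pre/post
#'     spirometry FVC and FEV1 (`x33`-`x36`).
#' }
#'
#' The schema ships as a machine-readable JSON file in
#' `system.file("extdata", "transplant_schema.json", package = "lripu")`;
#' this function reads it. The binary outcome `y` (six-month graft
#' survival, 1 = graft alive at six months) is not part of the schema.
#'
#' @return A `covariate_schema`: a data frame with one row per covariate and
#'   columns `tag`, `index`, `name`, `kind` (`"binary"`, `"dummy"` or
#'   `"continuous"`), `source` (the raw record field), `category` (for
#'   dummies) and `note` (units / coding).
#' @export
transplant_schema <- function() {
  path <- system.file("extdata", "transplant_schema.json", package = "lripu")
  if (!nzchar(path)) stop("bundled schema file not found; is the package installed?")
  read_schema(path)
}

#' Read a covariate schema from a JSON file
#'
#' @param path path to a JSON file with fields `tag`, `name`, `kind`,
#'   `source`, `category`, `note` per covariate.
#' @return A validated `covariate_schema`.
#' @export
read_schema <- function(path) {
  df <- jsonlite::fromJSON(path)
  df$category[is.na(df$category)] <- NA_character_
  df$index <- as.integer(sub("^x", "", df$tag))
  schema <- structure(df[order(df$index), , drop = FALSE],
                      class = c("covariate_schema", "data.frame"))
  rownames(schema) <- NULL
  validate_schema(schema)
  schema
}

#' Validate a covariate schema
#'
#' Checks the structural invariants: exactly 36 covariates tagged `x1`-`x36`
#' in order, dummy groups that partition their source categorical exactly as
#' the study schema lists them, and the fixed binary/continuous index sets.
#'
#' @param schema a `covariate_schema`.
#' @return The schema, invisibly; errors if any invariant is violated.
#' @export
validate_schema <- function(schema) {
  stopifnot(is.data.frame(schema))
  if (nrow(schema) != 36L) stop("schema must have exactly 36 covariates")
  if (!identical(schema$tag, paste0("x", 1:36)))
    stop("schema tags must be x1...x36, unique and in order")
  groups <- list(
    desease2  = paste0("x", 3:7),
    pre_tx    = paste0("x", 8:10),
    death_d   = paste0("x", 13:17),
    type_tx   = paste0("x", 20:24),
    cold_isch = paste0("x", 25:28)
  )
  for (src in names(groups)) {
    got <- schema$tag[schema$kind == "dummy" & schema$source == src]
    if (!identical(sort(got), sort(groups[[src]])))
      stop("dummy group for '", src, "' must be exactly {",
           paste(groups[[src]], collapse = ", "), "}")
    cats <- schema$category[match(groups[[src]], schema$tag)]
    if (anyNA(cats) || anyDuplicated(cats))
      stop("dummy categories for '", src, "' must be present and unique")
  }
  if (!setequal(schema$tag[schema$kind == "binary"], paste0("x", c(1, 11, 29, 30))))
    stop("binary covariates must be {x1, x11, x29, x30}")
  if (!setequal(schema$tag[schema$kind == "continuous"],
                paste0("x", c(2, 12, 18, 19, 31:36))))
    stop("continuous covariates must be {x2, x12, x18, x19, x31...x36}")
  invisible(schema)
}

#' Category levels of each categorical source variable
#'
#' @param schema a `covariate_schema`.
#' @return Named list mapping each categorical source variable to its
#'   category labels, in covariate-index order.
#' @export
schema_categories <- function(schema) {
  dum <- schema[schema$kind == "dummy", , drop = FALSE]
  split(dum$category, dum$source)[unique(dum$source)]
}

# Source-variable fields a complete record must carry (outcome excluded).
schema_fields <- function(schema) unique(schema$source)

#' Encode one transplant record into the 36-covariate vector
#'
#' Applies the one-of-k encoding: each categorical value activates exactly
#' one dummy in its group, binaries are copied as 0/1, continuous values are
#' copied as-is (raw scale; see [scale_design()]).
#'
#' Binary conventions: recipient/donor sex accepts `1`/`0`, `"male"`/
#' `"female"`; bypass and tailoring accept `1`/`0`, `"YES"`/`"NO"`, or
#' logicals.
#'
#' @param record named list (or one-row data frame) keyed by source-variable
#'   name: `sex_rec`, `age_rec`, `desease2`, `pre_tx`, `sex_donor`,
#'   `age_donor`, `death_d`, `ti_in_do`, `io2_donor`, `type_tx`,
#'   `cold_isch`, `bypass`, `Tailor`, `po2_pre`, `pco2_pre`, `fvc_pre`,
#'   `fvc_prp`, `fev1_pre`, `fev1_prp`. An outcome field `y` is ignored.
#' @param schema a `covariate_schema`.
#' @return Numeric vector of length 36 named `x1`...`x36` (raw scale).
#' @export
encode <- function(record, schema = transplant_schema()) {
  record <- as.list(record)
  x <- stats::setNames(numeric(36), schema$tag)
  for (i in seq_len(nrow(schema))) {
    row <- schema[i, ]
    val <- record[[row$source]]
    if (is.null(val) || (length(val) == 1L && is.na(val)))
      stop("missing value for mandatory field '", row$source, "'",
           call. = FALSE)
    x[i] <- switch(row$kind,
      binary     = encode_binary(val, row$source),
      continuous = encode_continuous(val, row$source),
      dummy      = {
        cats <- schema$category[schema$source == row$source]
        if (!as.character(val) %in% cats)
          stop("unknown category '", val, "' for variable '", row$source,
               "' (expected one of: ", paste(cats, collapse = ", "), ")",
               call. = FALSE)
        as.numeric(as.character(val) == row$category)
      })
  }
  x
}

encode_binary <- function(val, field) {
  if (is.logical(val)) return(as.numeric(val))
  if (is.numeric(val)) {
    if (!val %in% c(0, 1))
      stop("binary field '", field, "' must be 0/1, got ", val, call. = FALSE)
    return(as.numeric(val))
  }
  v <- toupper(as.character(val))
  if (v %in% c("MALE", "YES", "1", "TRUE")) return(1)
  if (v %in% c("FEMALE", "NO", "0", "FALSE")) return(0)
  stop("cannot interpret value '", val, "' for binary field '", field, "'",
       call. = FALSE)
}

encode_continuous <- function(val, field) {
  v <- suppressWarnings(as.numeric(val))
  if (is.na(v) || !is.finite(v))
    stop("non-numeric value '", val, "' for continuous field '", field, "'",
         call. = FALSE)
  v
}

#' Decode a covariate vector back to a raw record
#'
#' Inverse of [encode()] on schema-valid vectors: dummy groups are collapsed
#' back to their category label, binaries and continuous values copied.
#'
#' @param x numeric vector of length 36 (raw scale).
#' @param schema a `covariate_schema`.
#' @return Named list of raw field values.
#' @export
decode <- function(x, schema = transplant_schema()) {
  stopifnot(length(x) == 36L)
  rec <- list()
  for (src in schema_fields(schema)) {
    rows <- schema[schema$source == src, , drop = FALSE]
    if (rows$kind[1] == "dummy") {
      on <- which(x[rows$index] == 1)
      if (length(on) != 1L)
        stop("dummy group '", src, "' is not one-hot in the vector")
      rec[[src]] <- rows$category[on]
    } else {
      rec[[src]] <- unname(x[rows$index[1]])
    }
  }
  rec
}

#' Encode a table of transplant records into a raw design matrix
#'
#' Vectorised encoding of a data frame whose columns use the source-variable
#' names (the layout produced by [simulate_cohort()] and accepted by
#' [read_cohort()]). Rows with missing values are handled per `na_action`.
#'
#' @param records data frame of raw records; an optional `y` column is used
#'   as the outcome.
#' @param schema a `covariate_schema`.
#' @param na_action `"omit"` (default: complete-case removal), `"impute"`
#'   (median for continuous, mode for categorical/binary) or `"error"`.
#' @return A raw [design_matrix()] with `n` rows and 36 columns.
#' @export
encode_records <- function(records, schema = transplant_schema(),
                           na_action = c("omit", "impute", "error")) {
  na_action <- match.arg(na_action)
  records <- as.data.frame(records)
  fields <- schema_fields(schema)
  missing_fields <- setdiff(fields, names(records))
  if (length(missing_fields))
    stop("records lack mandatory field(s): ",
         paste(missing_fields, collapse = ", "), call. = FALSE)
  y <- if ("y" %in% names(records)) records$y else NULL

  incomplete <- rowSums(is.na(records[fields])) > 0
  if (any(incomplete)) {
    if (na_action == "error")
      stop(sum(incomplete), " record(s) have missing values", call. = FALSE)
    if (na_action == "omit") {
      records <- records[!incomplete, , drop = FALSE]
      if (!is.null(y)) y <- y[!incomplete]
    } else {
      for (f in fields) {
        miss <- is.na(records[[f]])
        if (!any(miss)) next
        records[[f]][miss] <- if (is.numeric(records[[f]]) &&
                                  schema$kind[match(f, schema$source)] == "continuous") {
          stats::median(records[[f]], na.rm = TRUE)
        } else {
          vals <- records[[f]][!miss]
          names(sort(table(vals), decreasing = TRUE))[1]
        }
      }
    }
  }
  if (nrow(records) == 0L) stop("no complete records to encode", call. = FALSE)

  X <- matrix(0, nrow(records), 36L,
              dimnames = list(NULL, schema$tag))
  for (i in seq_len(nrow(schema))) {
    row <- schema[i, ]
    col <- records[[row$source]]
    X[, i] <- switch(row$kind,
      binary     = vapply(col, encode_binary, numeric(1), field = row$source),
      continuous = vapply(col, encode_continuous, numeric(1), field = row$source),
      dummy      = {
        vals <- as.character(col)
        cats <- schema$category[schema$source == row$source]
        bad <- !vals %in% cats
        if (any(bad))
          stop("unknown category '", vals[which(bad)[1]], "' for variable '",
               row$source, "'", call. = FALSE)
        as.numeric(vals == row$category)
      })
  }
  design_matrix(X, y = y, scaled = FALSE)
}

#' Construct a design matrix
#'
#' A light container for an n-by-p covariate matrix, its (optional) binary
#' outcome, and the scaling state: `scaled = FALSE` means raw covariate
#' values; `scaled = TRUE` means every column has been mapped into the
#' \[1, 2\] range (see [scale_design()]) and `scaling` records the training
#' per-column min/max used for the map.
#'
#' @param X numeric matrix (columns named `x1`... by default).
#' @param y optional binary outcome vector (0/1), length `nrow(X)`.
#' @param scaled logical flag.
#' @param scaling scaling record (list with `min`, `max`) when scaled.
#' @return An object of class `design_matrix`.
#' @export
design_matrix <- function(X, y = NULL, scaled = FALSE, scaling = NULL) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (!is.numeric(X) || any(!is.finite(X)))
    stop("design matrix must be numeric and finite")
  if (!is.null(y)) {
    y <- as.numeric(y)
    if (length(y) != nrow(X)) stop("outcome length must match rows")
    if (!all(y %in% c(0, 1))) stop("outcome entries must be 0/1")
  }
  if (scaled) {
    if (is.null(scaling)) stop("a scaled design matrix needs its scaling record")
    if (any(X < 1 - 1e-9) || any(X > 2 + 1e-9))
      stop("scaled design entries must lie in [1, 2]")
  }
  structure(list(X = X, y = y, scaled = scaled, scaling = scaling),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("design_matrix: %d records x %d covariates (%s)%s\n",
              nrow(x$X), ncol(x$X), if (x$scaled) "scaled to [1,2]" else "raw",
              if (is.null(x$y)) "" else sprintf(", outcome rate %.3f", mean(x$y))))
  invisible(x)
}

#' @export
dim.design_matrix <- function(x) dim(x$X)

#' Scale a raw design matrix into the \[1, 2\] range
#'
#' Each column is mapped affinely by `x' = 1 + (x - min)/(max - min)` using
#' the column's own min and max, so all covariates (binaries included:
#' 0 -> 1, 1 -> 2) land in \[1, 2\]. The per-column min/max are stored in the
#' scaling record so new records can be transformed with the training
#' scaling via [apply_scaling()]. Strict positivity of the scaled values is
#' what makes non-integer powers in product units well defined.
#'
#' A constant column carries no information and would divide by zero; it is
#' mapped to all-1 (the multiplicative identity) with a warning.
#'
#' @param dm a raw [design_matrix()] with at least one row.
#' @return A scaled `design_matrix` carrying the scaling record.
#' @export
scale_design <- function(dm) {
  stopifnot(inherits(dm, "design_matrix"))
  if (dm$scaled) return(dm)
  if (nrow(dm$X) < 1L) stop("cannot scale an empty design matrix")
  mins <- apply(dm$X, 2, min)
  maxs <- apply(dm$X, 2, max)
  const <- maxs == mins
  if (any(const))
    warning("constant column(s) ", paste(colnames(dm$X)[const], collapse = ", "),
            " scaled to all-1", call. = FALSE)
  scaling <- list(min = mins, max = maxs)
  design_matrix(apply_scaling(scaling, dm$X, clip = FALSE), y = dm$y,
                scaled = TRUE, scaling = scaling)
}

#' Apply a stored training scaling to new raw values
#'
#' Maps raw values into \[1, 2\] with the training per-column min/max. Values
#' outside the training range would leave \[1, 2\] (and could produce
#' non-positive product-unit bases), so by default they are clipped back to
#' \[1, 2\] with a warning.
#'
#' @param scaling a scaling record (`list(min, max)` named by column).
#' @param X raw matrix or vector (length/columns matching the record).
#' @param clip clip out-of-range scaled values into \[1, 2\]?
#' @return Scaled matrix or vector.
#' @export
apply_scaling <- function(scaling, X, clip = TRUE) {
  vec <- is.null(dim(X))
  if (vec) X <- matrix(X, nrow = 1, dimnames = list(NULL, names(X)))
  if (ncol(X) != length(scaling$min))
    stop("scaling record has ", length(scaling$min), " columns, data has ", ncol(X))
  rng <- scaling$max - scaling$min
  S <- sweep(X, 2, scaling$min, "-")
  S <- sweep(S, 2, ifelse(rng == 0, 1, rng), "/") + 1
  S[, rng == 0] <- 1
  if (clip && (any(S < 1) || any(S > 2))) {
    warning("value(s) outside the training range clipped to [1, 2]",
            call. = FALSE)
    S[S < 1] <- 1
    S[S > 2] <- 2
  }
  if (vec) S[1, ] else S
}

#' Invert a stored scaling
#'
#' @param scaling a scaling record.
#' @param S scaled matrix or vector in \[1, 2\].
#' @return Raw-scale values (`min + (s - 1) * (max - min)`).
#' @export
inverse_scaling <- function(scaling, S) {
  vec <- is.null(dim(S))
  if (vec) S <- matrix(S, nrow = 1)
  rng <- scaling$max - scaling$min
  X <- sweep(sweep(S - 1, 2, rng, "*"), 2, scaling$min, "+")
  if (vec) X[1, ] else X
}

#' Read a cohort table from CSV or XLSX
#'
#' Column headers must use the source-variable names of the schema (plus an
#' optional outcome column `y`). XLSX reading requires the `readxl` package.
#'
#' @param path file path ending in `.csv` or `.xlsx`.
#' @return Data frame of raw records.
#' @export
read_cohort <- function(path) {
  if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("readxl", quietly = TRUE))
      stop("reading XLSX requires the 'readxl' package")
    as.data.frame(readxl::read_excel(path))
  } else {
    utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  }
}

#' Write an encoded design matrix as CSV
#'
#' Writes the covariate columns under their `x1`...`x36` headers, plus a
#' final `y` column when an outcome is present.
#'
#' @param dm a [design_matrix()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_design_csv <- function(dm, path) {
  df <- as.data.frame(dm$X)
  if (!is.null(dm$y)) df$y <- dm$y
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
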