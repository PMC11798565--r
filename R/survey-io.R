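#' Read / write a survey participant table
#'
#' Survey files are UTF-8 CSV with a header row and columns `id`,
#' `age_group`, `gender`, `region`, optionally `latent_class` and
#' `predicted_label`, then one column per feature. Demographic columns and
#' `latent_class` are restored to their canonical factor codings on read;
#' passing the feature `schema` additionally restores exact feature column
#' types (integer ordinals, character categoricals), making
#' `read_survey(write_survey(t), schema)` an identity.
#'
#' @param path File path.
#' @param schema Optional [feature_schema()] used to restore feature column
#'   types and check that all schema features are present.
#' @return `read_survey()` returns a participant tibble.
#' @export
read_survey <- function(path, schema = NULL) {
  # with a schema everything is read as text and converted explicitly, so
  # doubles are parsed by strtod (correctly rounded) and round-trip exactly
  tbl <- if (is.null(schema)) {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    readr::read_csv(path, col_types = readr::cols(.default = "c"),
                    progress = FALSE)
  }
  required <- c("id", "age_group", "gender", "region")
  missing <- setdiff(required, names(tbl))
  if (length(missing) > 0) {
    stop("survey file is missing required columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tbl <- as_cell_factors(tbl)
  tbl$id <- as.integer(tbl$id)
  if ("latent_class" %in% names(tbl)) {
    tbl$latent_class <- factor(as.character(tbl$latent_class),
                               levels = latent_classes())
  }
  if ("predicted_label" %in% names(tbl)) {
    tbl$predicted_label <- as.integer(tbl$predicted_label)
  }
  if (!is.null(schema)) {
    missing_f <- setdiff(schema$name, names(tbl))
    if (length(missing_f) > 0) {
      stop("survey file is missing feature columns: ",
           paste(missing_f, collapse = ", "), call. = FALSE)
    }
    for (i in seq_len(nrow(schema))) {
      nm <- schema$name[i]
      tbl[[nm]] <- switch(schema$type[i],
        continuous = as.double(tbl[[nm]]),
        ordinal = as.integer(tbl[[nm]]),
        categorical = as.character(tbl[[nm]])
      )
    }
  }
  feat_cols <- anyNA(tbl[setdiff(names(tbl), c("latent_class", "predicted_label"))])
  if (feat_cols) {
    stop("survey file contains missing values (blank answers are not allowed)",
         call. = FALSE)
  }
  tbl
}

#' @rdname read_survey
#' @param table A participant tibble.
#' @export
write_survey <- function(table, path) {
  stopifnot(all(c("id", "age_group", "gender", "region") %in% names(table)))
  out <- tibble::as_tibble(table)
  # 17 significant digits guarantee binary round-trip of doubles through text
  dbl <- vapply(out, is.double, logical(1))
  out[dbl] <- lapply(out[dbl], function(x) sprintf("%.17g", x))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
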