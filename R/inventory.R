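#' Column schema for inventory CSV files
#'
#' Maps the package's canonical record fields (`species`, `dbh`, `height`,
#' `age`, plus any named covariates) to the column names of a CSV file.
#' Defaults follow the canonical layout
#' `species, dbh_cm, height_m, age_yr, dem_m, p_mm, txn_c`. File columns not
#' mentioned in the schema are carried along verbatim as extra covariates.
#'
#' @param species,dbh,height,age file column names for the four required
#'   fields (DBH in cm, height in m, stand age in years).
#' @param covariates named character vector mapping covariate field names to
#'   file columns, e.g. `c(dem = "dem_m", p = "p_mm", txn = "txn_c")`.
#' @return named character vector (field -> file column) of class
#'   `inventory_schema`.
#' @export
inventory_schema <- function(species = "species", dbh = "dbh_cm",
                             height = "height_m", age = "age_yr",
                             covariates = c(dem = "dem_m", p = "p_mm",
                                            txn = "txn_c")) {
  out <- c(species = species, dbh = dbh, height = height, age = age,
           covariates)
  class(out) <- "inventory_schema"
  out
}

#' Read a stand-inventory table from CSV
#'
#' Reads plot records (species label, DBH, tree height, stand age and
#' per-plot environmental covariates), renames columns to canonical field
#' names via the schema, and drops rows whose DBH, height or age is missing
#' or non-positive. Dropped rows are counted in an audit attached as an
#' attribute (see [inventory_audit()]); they never abort the read.
#'
#' @param path CSV file path (header row, UTF-8, '.' decimal separator).
#' @param schema an [inventory_schema()].
#' @return a `data.frame` of class `inventory` with columns `species`,
#'   `dbh`, `height`, `age` and one column per covariate.
#' @export
read_inventory <- function(path, schema = inventory_schema()) {
  if (!file.exists(path)) stop_sg(sprintf("file not found: %s", path))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("species", "dbh", "height", "age")
  missing_cols <- setdiff(unname(schema[required]), names(raw))
  if (length(missing_cols))
    stop_sg(sprintf("schema error: column(s) not in file: %s",
                    paste(missing_cols, collapse = ", ")))
  # covariate mappings are optional: keep only those present in the file
  schema <- schema[c(required,
                     setdiff(names(schema), required)[
                       unname(schema[setdiff(names(schema), required)]) %in%
                         names(raw)])]
  out <- data.frame(species = as.character(raw[[schema[["species"]]]]),
                    stringsAsFactors = FALSE)
  for (f in c("dbh", "height", "age"))
    out[[f]] <- suppressWarnings(as.numeric(raw[[schema[[f]]]]))
  cov_fields <- setdiff(names(schema), required)
  for (f in cov_fields)
    out[[f]] <- suppressWarnings(as.numeric(raw[[schema[[f]]]]))
  extra <- setdiff(names(raw), unname(schema))
  for (f in extra) out[[f]] <- raw[[f]]

  n_in <- nrow(out)
  bad_missing <- !stats::complete.cases(out[c("dbh", "height", "age")])
  bad_nonpos <- !bad_missing & (out$dbh <= 0 | out$height <= 0 | out$age <= 0)
  keep <- !(bad_missing | bad_nonpos)
  audit <- list(n_input = n_in, n_retained = sum(keep),
                n_dropped = sum(!keep),
                n_missing = sum(bad_missing), n_nonpositive = sum(bad_nonpos))
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L) stop_sg("no valid records after filtering")
  as_inventory(out, audit)
}

as_inventory <- function(df, audit = NULL) {
  class(df) <- c("inventory", "data.frame")
  attr(df, "audit") <- audit %||%
    list(n_input = nrow(df), n_retained = nrow(df), n_dropped = 0L,
         n_missing = 0L, n_nonpositive = 0L)
  df
}

#' @describeIn read_inventory retrieve the row-filtering audit (input,
#'   retained and dropped-row counts) of a table returned by
#'   `read_inventory()`.
#' @param table an `inventory` table.
#' @export
inventory_audit <- function(table) attr(table, "audit")

#' Write an inventory table to CSV
#'
#' Numeric fields are written with 17 significant digits so that a
#' write/read round trip reproduces every value exactly.
#'
#' @param table an `inventory` data.frame.
#' @param path output CSV path.
#' @param schema an [inventory_schema()] giving the output column names; any
#'   table column without a schema entry keeps its name.
#' @return `path`, invisibly.
#' @export
write_inventory <- function(table, path, schema = inventory_schema()) {
  out <- as.data.frame(table)
  nm <- names(out)
  for (f in names(schema)) {
    i <- match(f, nm)
    if (!is.na(i)) nm[i] <- schema[[f]]
  }
  names(out) <- nm
  num <- vapply(out, is.numeric, TRUE)
  out[num] <- lapply(out[num], function(v) sprintf("%.17g", v))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @describeIn read_inventory names of the covariate columns of a table.
#' @export
covariate_names <- function(table) {
  setdiff(names(table), c("species", "dbh", "height", "age"))
}

#' Randomly partition an inventory table
#'
#' Splits rows into `length(fractions)` disjoint partitions whose sizes are
#' obtained by largest-remainder rounding of `fractions * n` (so the sizes
#' always sum to `n` exactly). With `stratify_by_species = TRUE` the rounding
#' and shuffling happen within each species separately. Identical
#' `seed` + input always yields the identical partition; the caller's RNG
#' stream is left untouched.
#'
#' @param table an inventory `data.frame`.
#' @param fractions positive fractions summing to 1, e.g. `c(0.7, 0.3)` for
#'   a modelling/validation split or `c(0.70, 0.15, 0.15)` for
#'   train/validation/test.
#' @param seed integer seed.
#' @param stratify_by_species logical.
#' @return list of `length(fractions)` inventory tables.
#' @examples
#' tab <- data.frame(species = "A", dbh = 1:10 + 0, height = 1, age = 1)
#' sapply(split_table(tab, c(0.7, 0.3), seed = 1), nrow)
#' @export
split_table <- function(table, fractions = c(0.7, 0.3), seed = 1L,
                        stratify_by_species = FALSE) {
  if (nrow(table) == 0L) stop_sg("cannot split an empty table")
  fractions <- as.numeric(fractions)
  if (any(fractions <= 0)) stop_sg("every fraction must be > 0")
  if (abs(sum(fractions) - 1) > 1e-9) stop_sg("fractions must sum to 1")
  part <- integer(nrow(table))
  with_seed(seed, {
    if (stratify_by_species) {
      for (sp in sort(unique(table$species))) {
        idx <- which(table$species == sp)
        sizes <- largest_remainder(length(idx), fractions)
        lab <- rep.int(seq_along(fractions), sizes)
        part[idx] <- lab[sample.int(length(idx))]
      }
    } else {
      sizes <- largest_remainder(nrow(table), fractions)
      lab <- rep.int(seq_along(fractions), sizes)
      part <- lab[sample.int(nrow(table))]
    }
  })
  if (any(tabulate(part, length(fractions)) == 0L))
    warning("a partition is empty (n too small for a fraction)",
            call. = FALSE)
  lapply(seq_along(fractions), function(i) {
    out <- table[part == i, , drop = FALSE]
    rownames(out) <- NULL
    as_inventory(out)
  })
}
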