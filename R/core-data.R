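# Core tabular types: sample metadata, feature (OTU) tables, per-sample
# chemistry / enzyme / P-fraction tables, and dataset validation.
#
# All tables are tibbles. A feature table carries features in rows
# (feature_id, domain, taxonomy) and one numeric count column per sample.

ENZYME_COLS <- c("BG", "CBH", "NAG", "LAP", "ALP")
PFRACTION_COLS <- c("CaCl2_P", "Citrate_P", "Enzyme_P", "HCl_P")
CHEMISTRY_COLS <- c(
  "pH", "SOM", "TN", "TP", "AK", "AP", "AN", "WEOC",
  "NO3N", "MBC", "MBN", "MBP", "yield"
)

#' Construct and validate sample metadata
#'
#' @param sample_id character vector of unique sample identifiers
#' @param treatment treatment labels; must be drawn from
#'   `c("CK","OPT","OPTN","OPTP","OPTM")`
#' @param replicate positive integer replicate index within treatment
#' @return a `soilpem_metadata` tibble with columns `sample_id`, `treatment`
#'   (factor in canonical order), `replicate`
#' @examples
#' sample_metadata(
#'   sample_id = c("s1", "s2", "s3", "s4"),
#'   treatment = c("CK", "CK", "OPT", "OPT"),
#'   replicate = c(1, 2, 1, 2)
#' )
#' @export
sample_metadata <- function(sample_id, treatment, replicate) {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id) > 0) {
    abort(paste0(
      "duplicated sample_id: ",
      paste(unique(sample_id[duplicated(sample_id)]), collapse = ", ")
    ))
  }
  bad <- setdiff(unique(as.character(treatment)), TREATMENTS)
  if (length(bad) > 0) {
    abort(paste0("unknown treatment label(s): ", paste(bad, collapse = ", ")))
  }
  replicate <- as.integer(replicate)
  if (any(is.na(replicate)) || any(replicate < 1)) {
    abort("replicate must be a positive integer")
  }
  out <- tibble(
    sample_id = sample_id,
    treatment = factor(as.character(treatment), levels = TREATMENTS),
    replicate = replicate
  )
  out$treatment <- droplevels(out$treatment)
  class(out) <- c("soilpem_metadata", class(out))
  out
}

#' Check whether a design is balanced
#'
#' Balanced means every treatment has the same replicate count. Imbalance is
#' advisory, not fatal: downstream statistics handle unequal group sizes.
#'
#' @param metadata a [sample_metadata()] tibble
#' @return logical scalar
#' @export
is_balanced_design <- function(metadata) {
  counts <- table(as.character(metadata$treatment))
  length(unique(as.integer(counts))) == 1L
}

#' Construct and validate a feature (OTU) count table
#'
#' @param counts non-negative integer matrix, features x samples, with
#'   column names matching `metadata$sample_id`
#' @param domain per-feature domain label: "bacteria", "fungi" or "archaea"
#' @param taxonomy per-feature rank-delimited taxonomy string
#'   (`"k__...;p__...;..."`)
#' @param metadata a [sample_metadata()] tibble; sample columns are reordered
#'   to metadata order
#' @param feature_id optional feature identifiers (default from rownames)
#' @return a `soilpem_features` tibble: `feature_id`, `domain`, `taxonomy`,
#'   then one count column per sample
#' @export
feature_table <- function(counts, domain, taxonomy, metadata,
                          feature_id = rownames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(feature_id)) feature_id <- paste0("OTU", seq_len(nrow(counts)))
  if (nrow(counts) < 1 || ncol(counts) < 2) {
    abort("feature table needs at least 1 feature and 2 samples")
  }
  missing <- setdiff(metadata$sample_id, colnames(counts))
  if (length(missing) > 0) {
    abort(paste0(
      "feature table is missing sample column(s): ",
      paste(missing, collapse = ", ")
    ))
  }
  extra <- setdiff(colnames(counts), metadata$sample_id)
  if (length(extra) > 0) {
    abort(paste0(
      "feature table has sample(s) absent from metadata: ",
      paste(extra, collapse = ", ")
    ))
  }
  counts <- counts[, metadata$sample_id, drop = FALSE]
  bad <- which(counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf(
      "negative or non-integer count at feature '%s', sample '%s'",
      feature_id[bad[1, 1]], colnames(counts)[bad[1, 2]]
    ))
  }
  bad_dom <- setdiff(unique(as.character(domain)), DOMAINS)
  if (length(bad_dom) > 0) {
    abort(paste0("unknown domain label(s): ", paste(bad_dom, collapse = ", ")))
  }
  out <- bind_cols(
    tibble(
      feature_id = as.character(feature_id),
      domain = as.character(rep_len(domain, nrow(counts))),
      taxonomy = as.character(rep_len(taxonomy, nrow(counts)))
    ),
    as_tibble(counts)
  )
  class(out) <- c("soilpem_features", class(out))
  out
}

#' Extract the count matrix from a feature table
#'
#' @param features a `soilpem_features` tibble
#' @return integer matrix, features x samples, rownames = feature ids
#' @export
feature_counts <- function(features) {
  m <- as.matrix(features[, setdiff(names(features),
                                    c("feature_id", "domain", "taxonomy"))])
  rownames(m) <- features$feature_id
  storage.mode(m) <- "double"
  m
}

#' Extract the phylum from a rank-delimited taxonomy string
#'
#' Looks for the `p__` token in a `;`-delimited lineage; returns
#' "unclassified" when absent or empty.
#'
#' @param taxonomy character vector of lineage strings
#' @return character vector of phylum names
#' @examples
#' parse_phylum("k__Bacteria;p__Actinobacteriota;c__Actinomycetia")
#' @export
parse_phylum <- function(taxonomy) {
  tok <- stringr::str_match(taxonomy, "(?:^|;)\\s*p__([^;]*)")[, 2]
  tok <- stringr::str_trim(tok)
  ifelse(is.na(tok) | tok == "", "unclassified", tok)
}

#' Read a feature table from tab-delimited text
#'
#' Expects a header row of sample ids; first column feature id; optional
#' `domain` and `taxonomy` columns; remaining columns integer counts.
#'
#' @param path file path
#' @param metadata a [sample_metadata()] tibble; columns are validated against
#'   it and reordered to metadata order
#' @return a `soilpem_features` tibble
#' @export
read_feature_table <- function(path, metadata) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(raw)[1] <- "feature_id"
  domain <- if ("domain" %in% names(raw)) raw$domain else "bacteria"
  taxonomy <- if ("taxonomy" %in% names(raw)) raw$taxonomy else NA_character_
  count_cols <- setdiff(names(raw), c("feature_id", "domain", "taxonomy"))
  counts <- as.matrix(raw[, count_cols])
  rownames(counts) <- raw$feature_id
  feature_table(counts, domain, taxonomy, metadata)
}

#' Write a feature table as tab-delimited text
#'
#' @param features a `soilpem_features` tibble
#' @param path output path
#' @return `path`, invisibly
#' @export
write_feature_table <- function(features, path) {
  readr::write_tsv(features, path, progress = FALSE)
  invisible(path)
}

# shared reader for per-sample numeric tables -------------------------------

read_sample_table <- function(path, required, optional = character()) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(raw)[1] <- "sample_id"
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    abort(paste0("missing column(s): ", paste(missing, collapse = ", ")))
  }
  raw[, c("sample_id", intersect(c(required, optional), names(raw)))]
}

#' Read the per-sample enzyme activity table (BG, CBH, NAG, LAP, ALP)
#' @param path tab-delimited file, first column sample id
#' @return tibble with sample_id plus the five activity columns
#' @export
read_enzyme_table <- function(path) {
  out <- read_sample_table(path, ENZYME_COLS)
  check_nonnegative(out, ENZYME_COLS, "enzyme activity")
  out
}

#' Read the per-sample phosphorus fraction table
#' @inheritParams read_enzyme_table
#' @return tibble with sample_id plus CaCl2_P, Citrate_P, Enzyme_P, HCl_P
#' @export
read_pfraction_table <- function(path) {
  out <- read_sample_table(path, PFRACTION_COLS)
  check_nonnegative(out, PFRACTION_COLS, "P fraction")
  out
}

#' Read the per-sample soil chemistry table
#' @inheritParams read_enzyme_table
#' @return tibble with sample_id plus chemistry columns (yield optional)
#' @export
read_soil_chemistry <- function(path) {
  out <- read_sample_table(path, setdiff(CHEMISTRY_COLS, "yield"), "yield")
  check_nonnegative(out, setdiff(intersect(CHEMISTRY_COLS, names(out)), "pH"),
                    "concentration")
  if (any(out$pH <= 0 | out$pH >= 14, na.rm = TRUE)) {
    abort("pH out of (0, 14)")
  }
  out
}

check_nonnegative <- function(tab, cols, what) {
  for (cl in cols) {
    if (any(tab[[cl]] < 0, na.rm = TRUE)) {
      abort(sprintf("negative %s in column '%s'", what, cl))
    }
  }
  invisible(tab)
}

#' Write a per-sample table as tab-delimited text
#' @param tab tibble with a `sample_id` column
#' @param path output path
#' @return `path`, invisibly
#' @export
write_sample_table <- function(tab, path) {
  readr::write_tsv(tab, path, progress = FALSE)
  invisible(path)
}

# dataset validation ---------------------------------------------------------

#' Validate a dataset against its metadata
#'
#' Produces a findings report rather than failing: each finding carries a
#' severity (`"fatal"` or `"advisory"`). Fatal findings are missing samples,
#' missing values or negative values; design imbalance is advisory. Findings
#' are independent of sample or feature order.
#'
#' @param metadata a [sample_metadata()] tibble
#' @param features optional `soilpem_features` table or named list of them
#' @param chemistry,enzymes,pfractions optional per-sample tibbles
#' @return a `soilpem_validation` tibble with columns `table`, `severity`,
#'   `message`
#' @export
validate_dataset <- function(metadata, features = NULL, chemistry = NULL,
                             enzymes = NULL, pfractions = NULL) {
  findings <- list()
  add <- function(table, severity, message) {
    findings[[length(findings) + 1]] <<- tibble(
      table = table, severity = severity, message = message
    )
  }

  if (!is_balanced_design(metadata)) {
    add("metadata", "advisory", "unbalanced design: replicate counts differ across treatments")
  }

  check_samples <- function(tab, name) {
    missing <- setdiff(metadata$sample_id, tab$sample_id)
    for (s in sort(missing)) {
      add(name, "fatal", paste0("sample missing: ", s))
    }
    num <- tab[, vapply(tab, is.numeric, logical(1)), drop = FALSE]
    if (anyNA(num)) add(name, "fatal", "missing numeric values")
    if (any(vapply(num, function(x) any(x < 0, na.rm = TRUE), logical(1)))) {
      add(name, "fatal", "negative values")
    }
  }

  if (!is.null(features)) {
    if (inherits(features, "soilpem_features")) features <- list(features = features)
    for (nm in names(features)) {
      ft <- features[[nm]]
      missing <- setdiff(metadata$sample_id, names(ft))
      for (s in sort(missing)) add(nm, "fatal", paste0("sample missing: ", s))
      cm <- feature_counts(ft)
      if (any(cm < 0)) add(nm, "fatal", "negative counts")
      if (any(colSums(cm) == 0)) add(nm, "advisory", "sample(s) with zero total count")
    }
  }
  if (!is.null(chemistry)) check_samples(chemistry, "chemistry")
  if (!is.null(enzymes)) check_samples(enzymes, "enzymes")
  if (!is.null(pfractions)) check_samples(pfractions, "pfractions")

  out <- if (length(findings) == 0) {
    tibble(table = character(), severity = character(), message = character())
  } else {
    bind_rows(findings)
  }
  out <- arrange(out, .data$table, .data$severity, .data$message)
  class(out) <- c("soilpem_validation", class(out))
  out
}

#' Does a validation report contain fatal findings?
#' @param report a [validate_dataset()] result
#' @return logical scalar
#' @export
has_fatal <- function(report) {
  any(report$severity == "fatal")
}
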