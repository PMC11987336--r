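# Reaction record parsing, multi-product decomposition, dataset IO.

.datatable.aware <- TRUE
#
# Interchange format is reaction SMILES "reactants>reagents>products" with
# "."-separated molecules per role.  Molecules are canonicalized on ingest and
# atom maps are stripped, so equality checks are notation-independent.

#' Construct a single-product reaction record
#'
#' @param record_id opaque identifier string.
#' @param product SMILES of exactly one connected molecule.
#' @param reactants character vector of reactant SMILES (length >= 1).
#' @param reagents character vector of reagent SMILES (may be empty).
#' @param attributes named numeric vector/list of conditions and measurements
#'   (e.g. `temperature` in degrees C, `yield` in percent); all finite.
#' @param meta named character list of free-form metadata.
#' @param canonicalize canonicalize all molecule notations (default TRUE).
#' @return object of class `rxn_record`.
#' @export
reaction_record <- function(record_id, product, reactants,
                            reagents = character(0),
                            attributes = list(), meta = list(),
                            canonicalize = TRUE) {
  stopifnot(is.character(record_id), length(record_id) == 1L)
  if (length(reactants) < 1L) {
    stop("record ", record_id, ": reactants must be non-empty")
  }
  if (canonicalize) {
    product <- canonical_smiles(product)
    reactants <- vapply(reactants, canonical_smiles, "", USE.NAMES = FALSE)
    reagents <- if (length(reagents)) {
      vapply(reagents, canonical_smiles, "", USE.NAMES = FALSE)
    } else character(0)
  }
  pmols <- parse_molecule_set(product)
  if (sum(vapply(pmols, mol_components, 0L)) != 1L) {
    stop("record ", record_id, ": product must be a single connected molecule, got ",
         product)
  }
  attributes <- .clean_attributes(attributes, record_id)
  structure(list(record_id = record_id, product = product,
                 reactants = reactants, reagents = reagents,
                 attributes = attributes, meta = meta),
            class = "rxn_record")
}

.clean_attributes <- function(attributes, record_id) {
  if (length(attributes) == 0L) return(list())
  vals <- lapply(attributes, function(x) as.numeric(x)[1])
  keep <- !vapply(vals, is.na, TRUE)
  vals <- vals[keep]
  if (any(!vapply(vals, is.finite, TRUE))) {
    stop("record ", record_id, ": non-finite attribute value")
  }
  vals
}

#' Parse one reaction SMILES line into a (possibly multi-product) raw reaction
#'
#' @param line reaction SMILES "reactants>reagents>products".
#' @param attributes named numeric conditions/measurements for the record.
#' @param meta named character metadata; `meta$id` seeds derived record ids.
#' @return object of class `rxn_raw` with canonicalized molecule lists.
#' @export
parse_reaction <- function(line, attributes = list(), meta = list()) {
  parts <- strsplit(line, ">", fixed = TRUE)[[1]]
  # strsplit drops trailing empties: "a>>" -> c("a",""); pad to 3
  if (lengths(regmatches(line, gregexpr(">", line, fixed = TRUE))) != 2L) {
    stop("reaction string must have exactly 3 '>'-separated fields: ", line)
  }
  parts <- c(parts, rep("", 3L - length(parts)))
  split_role <- function(s, role) {
    toks <- strsplit(s, ".", fixed = TRUE)[[1]]
    toks <- toks[nzchar(toks)]
    vapply(toks, function(t) {
      tryCatch(canonical_smiles(t),
               error = function(e) stop("unparsable ", role, " molecule '", t,
                                        "' in reaction: ", line, " (",
                                        conditionMessage(e), ")",
                                        call. = FALSE))
    }, "", USE.NAMES = FALSE)
  }
  reactants <- split_role(parts[1], "reactant")
  reagents <- split_role(parts[2], "reagent")
  products <- split_role(parts[3], "product")
  if (length(products) == 0L) {
    stop("reaction has no product: ", line)
  }
  structure(list(products = products, reactants = reactants,
                 reagents = reagents,
                 attributes = .clean_attributes(attributes, "raw"),
                 meta = meta),
            class = "rxn_raw")
}

#' Decompose a raw reaction into single-product records
#'
#' A raw reaction with k products yields exactly k records sharing the same
#' reactants, reagents and attributes.  Duplicate products yield duplicate
#' records (deduplication is a user-level filter).  Derived ids are
#' deterministic: the parent id as-is for k = 1, otherwise `<parent>_<index>`.
#'
#' @param raw an `rxn_raw`.
#' @param parent_id id of the parent record; defaults to `raw$meta$id` or "r".
#' @return list of `rxn_record`.
#' @export
decompose_multiproduct <- function(raw, parent_id = NULL) {
  stopifnot(inherits(raw, "rxn_raw"))
  if (is.null(parent_id)) {
    parent_id <- if (!is.null(raw$meta$id)) as.character(raw$meta$id) else "r"
  }
  k <- length(raw$products)
  lapply(seq_len(k), function(i) {
    rid <- if (k == 1L) parent_id else paste0(parent_id, "_", i)
    reaction_record(rid, raw$products[i], raw$reactants, raw$reagents,
                    raw$attributes, raw$meta, canonicalize = FALSE)
  })
}

#' Reaction-SMILES string of a single-product record
#' @param record an `rxn_record`.
#' @return "reactants>reagents>product" string.
#' @export
reaction_smiles <- function(record) {
  paste0(paste(record$reactants, collapse = "."), ">",
         paste(record$reagents, collapse = "."), ">", record$product)
}

#' Read a reaction dataset (CSV or JSONL) into single-product records
#'
#' CSV files carry a `reaction` column plus optional numeric attribute columns
#' and an optional `id` column.  JSONL files carry explicit
#' `product`/`reactants`/`reagents` arrays per line plus optional `id`,
#' `attributes` and `meta` objects.  Every row is parsed with
#' [parse_reaction()] (or assembled directly for JSONL) and decomposed with
#' [decompose_multiproduct()]; row order is preserved.
#'
#' @param path file path.
#' @param format "csv" or "jsonl" (default: inferred from extension).
#' @param reaction_col CSV column holding the reaction SMILES.
#' @param attr_cols CSV attribute columns (default: all numeric columns other
#'   than id/reaction).
#' @param on_error "fail" (default) stops at the first malformed row with its
#'   row number; "skip" drops malformed rows with a warning listing them.
#' @return list of `rxn_record`.
#' @export
read_dataset <- function(path, format = NULL, reaction_col = "reaction",
                         attr_cols = NULL, on_error = c("fail", "skip")) {
  on_error <- match.arg(on_error)
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(format)) {
    format <- if (grepl("\\.jsonl$", path)) "jsonl" else "csv"
  }
  records <- list()
  bad <- integer(0); bad_msg <- character(0)
  if (format == "csv") {
    dt <- data.table::fread(path, colClasses = NULL, showProgress = FALSE)
    if (nrow(dt) == 0L) return(list())
    if (!reaction_col %in% names(dt)) {
      stop("missing required column '", reaction_col, "' in ", path)
    }
    if (is.null(attr_cols)) {
      attr_cols <- names(dt)[vapply(dt, is.numeric, TRUE)]
      attr_cols <- setdiff(attr_cols, c("id", reaction_col))
    }
    meta_cols <- grep("^meta_", names(dt), value = TRUE)
    for (i in seq_len(nrow(dt))) {
      res <- tryCatch({
        attrs <- as.list(dt[i, attr_cols, with = FALSE])
        meta <- as.list(dt[i, meta_cols, with = FALSE])
        names(meta) <- sub("^meta_", "", meta_cols)
        absent <- vapply(meta, function(x) {
          is.na(x[1]) || (is.character(x) && !nzchar(x[1]))
        }, TRUE)
        meta <- lapply(meta[!absent], as.character)
        pid <- if ("id" %in% names(dt)) as.character(dt$id[i])
               else paste0("row", i)
        raw <- parse_reaction(dt[[reaction_col]][i], attrs, meta)
        decompose_multiproduct(raw, parent_id = pid)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        if (on_error == "fail") {
          stop("row ", i, " of ", path, ": ", conditionMessage(res))
        }
        bad <- c(bad, i); bad_msg <- c(bad_msg, conditionMessage(res))
      } else {
        records <- c(records, res)
      }
    }
  } else if (format == "jsonl") {
    lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
    lines <- lines[nzchar(lines)]
    for (i in seq_along(lines)) {
      res <- tryCatch({
        obj <- jsonlite::fromJSON(lines[i], simplifyVector = TRUE)
        rid <- if (!is.null(obj$id)) as.character(obj$id) else paste0("row", i)
        attrs <- if (!is.null(obj$attributes)) as.list(obj$attributes) else list()
        meta <- if (!is.null(obj$meta)) lapply(as.list(obj$meta), as.character)
                else list()
        products <- as.character(obj$product)
        raw <- structure(list(
          products = vapply(products, canonical_smiles, "", USE.NAMES = FALSE),
          reactants = vapply(as.character(obj$reactants), canonical_smiles, "",
                             USE.NAMES = FALSE),
          reagents = if (length(obj$reagents)) {
            vapply(as.character(obj$reagents), canonical_smiles, "",
                   USE.NAMES = FALSE)
          } else character(0),
          attributes = .clean_attributes(attrs, rid),
          meta = meta), class = "rxn_raw")
        decompose_multiproduct(raw, parent_id = rid)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        if (on_error == "fail") {
          stop("line ", i, " of ", path, ": ", conditionMessage(res))
        }
        bad <- c(bad, i); bad_msg <- c(bad_msg, conditionMessage(res))
      } else {
        records <- c(records, res)
      }
    }
  } else {
    stop("unknown dataset format: ", format)
  }
  if (length(bad)) {
    warning("skipped ", length(bad), " malformed row(s): ",
            paste(bad, collapse = ", "))
  }
  records
}

#' Write single-product records to CSV or JSONL
#'
#' Round-trip guarantee: `read_dataset(write_dataset(x))` reproduces the
#' records field-for-field (ids, molecules, attributes, metadata).
#'
#' @param records list of `rxn_record`.
#' @param path output path.
#' @param format "csv" or "jsonl" (default inferred from extension).
#' @export
write_dataset <- function(records, path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.jsonl$", path)) "jsonl" else "csv"
  }
  if (format == "csv") {
    attr_keys <- sort(unique(unlist(lapply(records, function(r)
      names(r$attributes)))))
    meta_keys <- sort(unique(unlist(lapply(records, function(r)
      setdiff(names(r$meta), "id")))))
    rows <- lapply(records, function(r) {
      row <- list(id = r$record_id, reaction = reaction_smiles(r))
      for (k in attr_keys) {
        row[[k]] <- if (!is.null(r$attributes[[k]])) r$attributes[[k]] else NA_real_
      }
      for (k in meta_keys) {
        row[[paste0("meta_", k)]] <- if (!is.null(r$meta[[k]])) r$meta[[k]]
                                     else NA_character_
      }
      row
    })
    dt <- data.table::rbindlist(rows)
    data.table::fwrite(dt, path, bom = FALSE)
  } else if (format == "jsonl") {
    con <- file(path, open = "w", encoding = "UTF-8")
    on.exit(close(con))
    for (r in records) {
      obj <- list(id = r$record_id, product = r$product,
                  reactants = as.list(r$reactants),
                  reagents = as.list(r$reagents),
                  attributes = r$attributes,
                  meta = r$meta[setdiff(names(r$meta), "id")])
      writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), con)
    }
  } else {
    stop("unknown dataset format: ", format)
  }
  invisible(NULL)
}
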