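# MeSH vocabulary handling: descriptor records, loaders for the standard
# descriptor distribution formats, and top-level category membership.
#
# MeSH organizes ~30,000 descriptors into 16 top-level categories; the first
# character of a tree number (e.g. "C04.588") is the category letter. The
# differential analysis is restricted by default to Diseases (C), Chemicals
# and Drugs (D), and Analytical, Diagnostic and Therapeutic Techniques and
# Equipment (E), subcategories included (matching is by first letter only).

.tree_number_re <- "^[A-Z][0-9]+(\\.[0-9]+)*$"

#' Construct a MeSH descriptor
#'
#' A descriptor is a controlled-vocabulary term together with its positions
#' in the MeSH tree. The `categories` field is always derived from the tree
#' numbers (unique first letters) and never stored independently; a
#' descriptor without tree numbers has no categories.
#'
#' @param ui Descriptor unique identifier (scalar character).
#' @param name Preferred descriptor label (scalar character).
#' @param tree_numbers Character vector of dot-separated tree codes such as
#'   `"C04.588"`. May be empty.
#' @return An object of class `mesh_descriptor`: a list with fields `ui`,
#'   `name`, `tree_numbers` and `categories`.
#' @examples
#' d <- mesh_descriptor("D000001", "Calcimycin", "D03.633.100.221.173")
#' d$categories  # "D"
#' @export
mesh_descriptor <- function(ui, name, tree_numbers = character()) {
  stopifnot(is.character(ui), length(ui) == 1L, nzchar(ui),
            is.character(name), length(name) == 1L, nzchar(name))
  tree_numbers <- as.character(tree_numbers)
  bad <- tree_numbers[!grepl(.tree_number_re, tree_numbers)]
  if (length(bad) > 0L) {
    stop("malformed tree number(s) for '", name, "': ",
         paste(bad, collapse = ", "))
  }
  structure(
    list(ui = ui, name = name, tree_numbers = tree_numbers,
         categories = sort(unique(substr(tree_numbers, 1L, 1L)))),
    class = "mesh_descriptor"
  )
}

#' @export
print.mesh_descriptor <- function(x, ...) {
  cat("<mesh_descriptor> ", x$ui, " ", x$name, "\n", sep = "")
  cat("  tree numbers: ", paste(x$tree_numbers, collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Internal constructor shared by the file loaders and the synthetic
# generator. `descriptors` is a list of mesh_descriptor objects.
new_vocabulary <- function(descriptors) {
  uis <- vapply(descriptors, `[[`, character(1L), "ui")
  dup <- unique(uis[duplicated(uis)])
  if (length(dup) > 0L) {
    stop("duplicate descriptor UI: ", paste(dup, collapse = ", "))
  }
  names(descriptors) <- uis
  structure(
    list(descriptors = descriptors,
         ui = uis,
         name_key = vapply(descriptors,
                           function(d) tolower(trimws(d$name)), character(1L))),
    class = "mesh_vocabulary"
  )
}

#' Load a MeSH vocabulary
#'
#' Reads a descriptor vocabulary from either the descriptor XML distribution
#' dialect (`DescriptorRecord` / `DescriptorUI` / `DescriptorName` /
#' `TreeNumberList`) or a 3-column TSV (`ui`, `name`, semicolon-joined tree
#' numbers). Descriptors without tree numbers are retained with empty
#' categories. Supplementary concept records and qualifiers are out of
#' scope: only descriptors are represented.
#'
#' @param path File path.
#' @param format `"tsv"` or `"mesh-xml"`.
#' @return A `mesh_vocabulary` object mapping descriptor names and UIs to
#'   descriptors (see [vocab_lookup()]).
#' @export
load_vocabulary <- function(path, format = c("tsv", "mesh-xml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("vocabulary file not found: ", path)
  descriptors <- switch(format,
    tsv        = parse_vocab_tsv(path),
    `mesh-xml` = parse_vocab_xml(path)
  )
  if (length(descriptors) == 0L) {
    warning("vocabulary file '", path, "' contains no descriptors")
  }
  new_vocabulary(descriptors)
}

parse_vocab_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 2L) {
      stop("vocabulary parse error at line ", i,
           ": expected at least 2 tab-separated fields")
    }
    trees <- if (length(fields) >= 3L && nzchar(trimws(fields[[3L]]))) {
      tn <- trimws(strsplit(fields[[3L]], ";", fixed = TRUE)[[1L]])
      tn[nzchar(tn)]
    } else {
      character()
    }
    out[[i]] <- tryCatch(
      mesh_descriptor(trimws(fields[[1L]]), trimws(fields[[2L]]), trees),
      error = function(e) {
        stop("vocabulary parse error at line ", i, ": ",
             conditionMessage(e), call. = FALSE)
      }
    )
  }
  out
}

parse_vocab_xml <- function(path) {
  doc <- xml2::read_xml(path)
  recs <- xml2::xml_find_all(doc, ".//DescriptorRecord")
  lapply(recs, function(r) {
    ui <- xml2::xml_text(xml2::xml_find_first(r, "./DescriptorUI"))
    nm <- xml2::xml_text(xml2::xml_find_first(r, "./DescriptorName/String"))
    if (is.na(ui) || is.na(nm) || !nzchar(ui) || !nzchar(nm)) {
      stop("malformed DescriptorRecord: missing DescriptorUI or DescriptorName")
    }
    trees <- xml2::xml_text(
      xml2::xml_find_all(r, "./TreeNumberList/TreeNumber"))
    mesh_descriptor(ui, nm, trees)
  })
}

#' @export
length.mesh_vocabulary <- function(x) length(x$descriptors)

#' @export
print.mesh_vocabulary <- function(x, ...) {
  cats <- sort(unique(unlist(lapply(x$descriptors, `[[`, "categories"))))
  cat("<mesh_vocabulary> ", length(x$descriptors), " descriptors, categories {",
      paste(cats, collapse = ","), "}\n", sep = "")
  invisible(x)
}

#' Look up descriptors by name or UI
#'
#' Terms are matched first by UI (exact), then by name, case-insensitively
#' after trimming whitespace, so that article term lists and vocabulary
#' entries resolve consistently. UI and name lookup resolve to the same
#' descriptor object.
#'
#' @param vocab A `mesh_vocabulary`.
#' @param terms Character vector of descriptor names or UIs.
#' @return A list, parallel to `terms`, of `mesh_descriptor` objects, with
#'   `NULL` for unmapped terms.
#' @export
vocab_lookup <- function(vocab, terms) {
  stopifnot(inherits(vocab, "mesh_vocabulary"))
  i <- match(terms, vocab$ui)
  miss <- is.na(i)
  i[miss] <- match(tolower(trimws(terms[miss])), vocab$name_key)
  out <- vector("list", length(terms))
  hit <- !is.na(i)
  out[hit] <- vocab$descriptors[i[hit]]
  names(out) <- terms
  out
}

#' Test whether a descriptor belongs to any allowed category
#'
#' Returns `TRUE` iff the descriptor's category set intersects `allowed`.
#' Subcategories are implicitly included because membership is decided by
#' the first letter of the tree numbers alone.
#'
#' @param descriptor A `mesh_descriptor`, or a character vector of category
#'   letters (e.g. the `categories` field itself).
#' @param allowed Non-empty set of single uppercase letters, e.g.
#'   `c("C", "D", "E")`.
#' @return Scalar logical.
#' @examples
#' in_categories(mesh_descriptor("D01", "x", "C04.588"), c("C", "D", "E"))
#' @export
in_categories <- function(descriptor, allowed) {
  if (length(allowed) == 0L || !all(grepl("^[A-Z]$", allowed))) {
    stop("'allowed' must be a non-empty set of single uppercase letters")
  }
  cats <- if (inherits(descriptor, "mesh_descriptor")) {
    descriptor$categories
  } else {
    as.character(descriptor)
  }
  length(intersect(cats, allowed)) > 0L
}
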