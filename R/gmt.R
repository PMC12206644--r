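#' Construct a bidirectional gene signature
#'
#' A bidirectional signature is a named pair of disjoint gene sets: a
#' positive ("favorable") set expected high in the positive class and a
#' negative ("unfavorable") set expected high in the opposite class. The
#' fingerprint score is the positive sub-score minus the negative sub-score.
#'
#' @param name Signature name.
#' @param positive Character vector of gene ids in the favorable set.
#' @param negative Character vector of gene ids in the unfavorable set.
#' @return An object of class `bidir_signature`.
#' @export
bidir_signature <- function(name, positive, negative) {
  positive <- unique(as.character(positive))
  negative <- unique(as.character(negative))
  if (length(positive) == 0L || length(negative) == 0L) {
    stop("signature '", name, "': both positive and negative sets must be non-empty",
         call. = FALSE)
  }
  shared <- intersect(positive, negative)
  if (length(shared)) {
    stop("signature '", name, "': positive and negative sets share gene(s): ",
         paste(shared, collapse = ", "), call. = FALSE)
  }
  structure(list(name = name, positive = positive, negative = negative),
            class = "bidir_signature")
}

#' @export
print.bidir_signature <- function(x, ...) {
  cat(sprintf("bidir_signature '%s': %d positive / %d negative genes\n",
              x$name, length(x$positive), length(x$negative)))
  invisible(x)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated fields
#' `name<TAB>description<TAB>gene1<TAB>gene2...`. Empty gene fields are
#' dropped; a set with no genes is an error.
#'
#' @param path Path to the GMT file.
#' @return Named list of character vectors of gene ids.
#' @seealso [pair_signatures()] to combine `_UP`/`_DN` sets.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty GMT file: ", path, call. = FALSE)
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) {
      stop(sprintf("GMT parse error at line %d of %s: need name, description and >=1 gene",
                   i, path), call. = FALSE)
    }
    genes <- unique(fields[-(1:2)][nzchar(fields[-(1:2)])])
    if (!length(genes)) {
      stop(sprintf("GMT parse error at line %d of %s: set '%s' has no genes",
                   i, path, fields[1L]), call. = FALSE)
    }
    if (fields[1L] %in% names(sets)) {
      stop("duplicate set name in ", path, ": ", fields[1L], call. = FALSE)
    }
    sets[[fields[1L]]] <- genes
  }
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors, or a single
#'   [bidir_signature()] (written as two sets with suffixes).
#' @param path Output path.
#' @param description Description field (second GMT column) for every set.
#' @param up_suffix,dn_suffix Suffixes used when writing a signature.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(sets, path, description = ".",
                      up_suffix = "_UP", dn_suffix = "_DN") {
  if (inherits(sets, "bidir_signature")) {
    sets <- stats::setNames(
      list(sets$positive, sets$negative),
      paste0(sets$name, c(up_suffix, dn_suffix))
    )
  }
  stopifnot(is.list(sets), !is.null(names(sets)))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, description, sets[[nm]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Pair up/down gene sets into bidirectional signatures
#'
#' Matches every set named `<base><up_suffix>` with its `<base><dn_suffix>`
#' partner into a [bidir_signature()] named `<base>`. Sets without a partner
#' (or with neither suffix) are reported with a warning and skipped.
#'
#' @param sets Named list of gene sets as returned by [read_gmt()].
#' @param up_suffix Suffix marking the positive set (default `"_UP"`).
#' @param dn_suffix Suffix marking the negative set (default `"_DN"`).
#' @return List of `bidir_signature` objects, named by base name.
#' @export
pair_signatures <- function(sets, up_suffix = "_UP", dn_suffix = "_DN") {
  nms <- names(sets)
  is_up <- endsWith(nms, up_suffix)
  is_dn <- endsWith(nms, dn_suffix) & !is_up
  base_up <- substr(nms[is_up], 1L, nchar(nms[is_up]) - nchar(up_suffix))
  base_dn <- substr(nms[is_dn], 1L, nchar(nms[is_dn]) - nchar(dn_suffix))
  paired <- intersect(base_up, base_dn)
  unpaired <- c(nms[is_up][!base_up %in% paired],
                nms[is_dn][!base_dn %in% paired],
                nms[!is_up & !is_dn])
  if (length(unpaired)) {
    warning("unpaired gene set(s) skipped: ", paste(unpaired, collapse = ", "),
            call. = FALSE)
  }
  sigs <- lapply(paired, function(b) {
    bidir_signature(b,
                    positive = sets[[paste0(b, up_suffix)]],
                    negative = sets[[paste0(b, dn_suffix)]])
  })
  stats::setNames(sigs, paired)
}
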