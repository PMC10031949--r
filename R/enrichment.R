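#' Read a gene-set collection from a GMT file
#'
#' Standard tab-separated GMT: one set per line as
#' `name<TAB>description<TAB>member1<TAB>member2...`. Duplicate members
#' within a line are stored once; duplicate set names are an error. The
#' collection's default universe is the union of all members.
#'
#' @param path Path to a GMT file.
#' @return An object of class `gene_set_collection`: a list with `sets`
#'   (named list of character vectors), `descriptions` and `universe`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  sets <- list(); desc <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop(sprintf("malformed GMT line %d: expected name, description and >= 1 member", i),
           call. = FALSE)
    nm <- f[1]
    if (nm %in% names(sets))
      stop(sprintf("duplicate set name '%s' at line %d", nm, i), call. = FALSE)
    sets[[nm]] <- unique(f[-(1:2)])
    desc[nm] <- f[2]
  }
  structure(list(sets = sets, descriptions = desc,
                 universe = sort(unique(unlist(sets, use.names = FALSE)))),
            class = "gene_set_collection")
}

#' Write a gene-set collection to a GMT file
#'
#' @param collection A `gene_set_collection` (see [read_gmt()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, collection$descriptions[[nm]] %||% "", collection$sets[[nm]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Gene-set overrepresentation by the one-sided hypergeometric test
#'
#' For each set, tests whether the hit list overlaps it more than expected
#' under hypergeometric sampling from the universe (equivalently Fisher's
#' exact test, enrichment-only), and applies Bonferroni correction with
#' family size equal to the number of sets tested. Hits outside the universe
#' are dropped with a warning; sets are restricted to the universe.
#'
#' @param hits Character vector of molecule IDs.
#' @param collection A `gene_set_collection` from [read_gmt()].
#' @param universe Optional character vector overriding the collection's
#'   universe (e.g. a reference genome's gene list).
#' @param alpha Corrected-p cutoff for the `significant` flag.
#' @return Data frame per set: `set`, `size`, `overlap`, `expected`
#'   (`|hits| * |set| / |universe|`), `p` (upper-tail hypergeometric),
#'   `p_bonf`, `significant`; sorted by `p`.
#' @export
overrepresentation <- function(hits, collection, universe = NULL, alpha = 0.05) {
  if (!inherits(collection, "gene_set_collection"))
    stop("'collection' must be a gene_set_collection", call. = FALSE)
  universe <- unique(universe %||% collection$universe)
  hits <- unique(as.character(hits))
  outside <- setdiff(hits, universe)
  if (length(outside) > 0L) {
    warning(length(outside), " hit(s) outside the universe dropped", call. = FALSE)
    hits <- setdiff(hits, outside)
  }
  N <- length(universe); nh <- length(hits)
  rows <- lapply(names(collection$sets), function(nm) {
    set <- intersect(collection$sets[[nm]], universe)
    k <- length(intersect(hits, set))
    p <- if (nh == 0L || length(set) == 0L) 1
         else stats::phyper(k - 1, length(set), N - length(set), nh,
                            lower.tail = FALSE)
    data.frame(set = nm, size = length(set), overlap = k,
               expected = nh * length(set) / N, p = p)
  })
  out <- do.call(rbind, rows)
  out$p_bonf <- bonferroni_adjust(out$p)
  out$significant <- out$p_bonf < alpha
  out[order(out$p, out$set), , drop = FALSE]
}
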