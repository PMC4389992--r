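#' Read and write GMT gene-set files
#'
#' One set per line, tab-separated: name, description, member gene ids.
#'
#' @param path file path.
#' @return \code{readGmt} returns a \linkS4class{GeneSetCollection}.
#' @export
readGmt <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- lengths(parts) < 3L
    if (any(bad))
        stop("malformed GMT line(s): ", paste(which(bad), collapse = ", "))
    sets <- lapply(parts, function(p) p[-(1:2)])
    names(sets) <- vapply(parts, `[[`, character(1), 1L)
    GeneSetCollection(sets, vapply(parts, `[[`, character(1), 2L))
}

#' @rdname readGmt
#' @param gsc a \linkS4class{GeneSetCollection}.
#' @return \code{writeGmt} invisibly returns \code{path}.
#' @export
writeGmt <- function(gsc, path) {
    lines <- vapply(seq_along(gsc@sets), function(i)
        paste(c(names(gsc@sets)[i], gsc@description[i], gsc@sets[[i]]),
              collapse = "\t"), character(1))
    writeLines(lines, path)
    invisible(path)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment, monotone-enforced and capped at
#' 1, returned in input order. Input p-values must lie in (0, 1].
#'
#' @param p numeric vector of raw p-values.
#' @return adjusted p-values.
#' @export
bhAdjust <- function(p) {
    if (anyNA(p) || any(p <= 0 | p > 1))
        stop("p-values must lie in (0, 1]")
    stats::p.adjust(p, method = "BH")
}

#' Gene-set overrepresentation of selected features
#'
#' Upper-tail hypergeometric test per set: with universe size N, set size K
#' (after intersecting members with the universe), n selected genes and k of
#' them in the set, p = P(X >= k). Sets falling entirely outside the
#' universe are skipped with a warning. Benjamini-Hochberg adjusted values
#' are added and rows are sorted by them.
#'
#' @param selected character vector of selected gene ids (must be a subset
#'   of \code{universe}).
#' @param universe character vector: all genes eligible for selection (the
#'   analyzable protein-coding space, not the whole genome).
#' @param gsc a \linkS4class{GeneSetCollection}.
#' @param up,down optional disjoint id lists partitioning \code{selected}
#'   by direction; per-set counts \code{n_up}/\code{n_down} are added.
#' @return data.frame with columns \code{set_name}, \code{overlap},
#'   \code{set_size}, \code{n_selected}, \code{universe_size},
#'   \code{p_hyper}, \code{p_bh} (and \code{n_up}, \code{n_down} when
#'   direction lists are given), sorted by \code{p_bh}.
#' @export
hypergeometricEnrichment <- function(selected, universe, gsc,
                                     up = NULL, down = NULL) {
    selected <- unique(as.character(selected))
    universe <- unique(as.character(universe))
    off <- setdiff(selected, universe)
    if (length(off))
        stop("selected genes outside the universe: ",
             paste(utils::head(off, 5L), collapse = ", "),
             if (length(off) > 5L) sprintf(" (+%d more)", length(off) - 5L))
    N <- length(universe); n <- length(selected)

    members <- lapply(geneSets(gsc), intersect, universe)
    empty <- lengths(members) == 0L
    if (any(empty)) {
        warning("skipping set(s) with no members in the universe: ",
                paste(names(members)[empty], collapse = ", "))
        members <- members[!empty]
    }
    if (!length(members))
        return(data.frame(set_name = character(), overlap = integer(),
                          set_size = integer(), n_selected = integer(),
                          universe_size = integer(), p_hyper = numeric(),
                          p_bh = numeric(), stringsAsFactors = FALSE))

    K <- lengths(members)
    k <- vapply(members, function(mm) length(intersect(mm, selected)),
                integer(1))
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    out <- data.frame(set_name = names(members), overlap = k, set_size = K,
                      n_selected = n, universe_size = N, p_hyper = p,
                      p_bh = bhAdjust(p), stringsAsFactors = FALSE,
                      row.names = NULL)
    if (!is.null(up) || !is.null(down)) {
        comp <- directionComposition(
            GeneSetCollection(members, rep("", length(members))), up, down)
        out$n_up <- comp$n_up[match(out$set_name, comp$set_name)]
        out$n_down <- comp$n_down[match(out$set_name, comp$set_name)]
    }
    out[order(out$p_bh, out$p_hyper), , drop = FALSE]
}

#' Up/down composition of gene sets
#'
#' Counts each set's members among the up- and down-regulated selections
#' (mirroring pathway bar charts colouring up- vs down-regulated genes).
#'
#' @param gsc a \linkS4class{GeneSetCollection} (members already intersected
#'   with the analysis universe).
#' @param up,down disjoint character vectors of selected gene ids.
#' @return data.frame with \code{set_name}, \code{n_up}, \code{n_down},
#'   \code{frac_up}, \code{frac_down} (denominator: set size).
#' @export
directionComposition <- function(gsc, up, down) {
    up <- unique(as.character(up %||% character()))
    down <- unique(as.character(down %||% character()))
    if (length(intersect(up, down)))
        stop("up and down lists overlap")
    sets <- geneSets(gsc)
    nUp <- vapply(sets, function(s) length(intersect(s, up)), integer(1))
    nDn <- vapply(sets, function(s) length(intersect(s, down)), integer(1))
    sz <- lengths(sets)
    data.frame(set_name = names(sets), n_up = nUp, n_down = nDn,
               frac_up = nUp / sz, frac_down = nDn / sz,
               stringsAsFactors = FALSE, row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
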