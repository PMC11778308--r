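#' Ranked taxonomy used throughout the package
#'
#' Lineages follow the GTDB convention of prefixed, semicolon-separated rank
#' names from domain down to genus (`d__`, `p__`, `c__`, `o__`, `f__`,
#' `g__`). Ranks are filled left to right; a filled rank may never follow an
#' unresolved (empty) one.
#'
#' @name lineage
NULL

#' Taxonomic ranks, shallowest first
#' @export
GTDB_RANKS <- c("domain", "phylum", "class", "order", "family", "genus")

RANK_PREFIXES <- c(domain = "d__", phylum = "p__", class = "c__",
                   order = "o__", family = "f__", genus = "g__")

rank_index <- function(rank) {
  i <- match(rank, GTDB_RANKS)
  if (is.na(i)) {
    stop("unknown rank '", rank, "'; must be one of: ",
         paste(GTDB_RANKS, collapse = ", "), call. = FALSE)
  }
  i
}

#' Parse prefixed lineage strings
#'
#' Splits GTDB-style lineage strings (e.g.
#' `"d__Bacteria; p__Acidobacteriota; c__Terriglobia"`) into a
#' rank-by-lineage character matrix. Unresolved trailing ranks are `NA`.
#'
#' @param text character vector of prefixed lineage strings.
#' @return A character matrix with one row per input string and the six
#'   columns `domain` ... `genus`; unresolved ranks are `NA`.
#' @examples
#' parse_lineage("d__Bacteria; p__Acidobacteriota")
#' @export
parse_lineage <- function(text) {
  stopifnot(is.character(text))
  out <- matrix(NA_character_, nrow = length(text), ncol = length(GTDB_RANKS),
                dimnames = list(NULL, GTDB_RANKS))
  for (i in seq_along(text)) {
    fields <- trimws(strsplit(text[[i]], ";", fixed = TRUE)[[1]])
    if (length(fields) == 0L || length(fields) > length(GTDB_RANKS)) {
      stop("malformed lineage string: '", text[[i]], "'", call. = FALSE)
    }
    for (j in seq_along(fields)) {
      pref <- RANK_PREFIXES[[j]]
      if (substr(fields[[j]], 1L, 3L) != pref) {
        stop("malformed lineage '", text[[i]], "': field ", j,
             " ('", fields[[j]], "') does not carry the expected prefix '",
             pref, "'", call. = FALSE)
      }
      name <- substring(fields[[j]], 4L)
      out[i, j] <- if (nzchar(name)) name else NA_character_
    }
    filled <- !is.na(out[i, ])
    if (any(filled) && any(filled & cumsum(!filled) > 0L)) {
      stop("inconsistent lineage '", text[[i]],
           "': a filled rank follows an unresolved rank", call. = FALSE)
    }
  }
  out
}

#' Render a parsed lineage back to its prefixed string form
#'
#' Inverse of [parse_lineage()]: only the filled ranks are rendered, so the
#' round-trip is lossless.
#'
#' @param ranks character matrix (or single named vector) as produced by
#'   [parse_lineage()].
#' @return character vector of prefixed lineage strings.
#' @export
format_lineage <- function(ranks) {
  if (is.null(dim(ranks))) ranks <- matrix(ranks, nrow = 1,
                                           dimnames = list(NULL, names(ranks)))
  apply(ranks, 1L, function(r) {
    filled <- which(!is.na(r) & nzchar(r))
    if (length(filled) == 0L) return("")
    depth <- max(filled)
    paste0(RANK_PREFIXES[seq_len(depth)], r[seq_len(depth)],
           collapse = "; ")
  })
}

#' Depth (number of resolved ranks) of lineage strings
#' @param text character vector of prefixed lineage strings.
#' @return integer vector; 0 for an entirely unresolved lineage.
#' @export
lineage_depth <- function(text) {
  ranks <- parse_lineage(text)
  as.integer(rowSums(!is.na(ranks)))
}

#' Truncate lineage strings at a rank
#'
#' Lineages resolved beyond `rank` are cut back to it; lineages unresolved at
#' `rank` are returned unchanged (their deepest resolved prefix) and flagged.
#'
#' @param text character vector of prefixed lineage strings.
#' @param rank one of `r toString(GTDB_RANKS)`.
#' @return data.frame with columns `lineage` (truncated string) and
#'   `unresolved` (logical: lineage was not resolved at `rank`).
#' @export
truncate_lineage <- function(text, rank) {
  k <- rank_index(rank)
  ranks <- parse_lineage(text)
  depth <- as.integer(rowSums(!is.na(ranks)))
  keep <- ranks
  if (ncol(keep) > k) keep[, (k + 1L):ncol(keep)] <- NA_character_
  data.frame(lineage = format_lineage(keep),
             unresolved = depth < k,
             stringsAsFactors = FALSE)
}
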