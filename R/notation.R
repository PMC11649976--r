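#' Parse the hyphen-linked placement notation
#'
#' Ligand placements on the Template are written as hyphen-linked Ring
#' paths such as `"A(B)-E(G)-eE-F-L"`: the main path lists the Rings the
#' molecule traces, a parenthesised group attaches a branch to the
#' preceding main-path Ring, and a slash separates alternative Rings
#' (`"D/eE"`, read as either Ring acceptable).  An optional leading
#' `"Rings "` prefix and internal whitespace are ignored.
#'
#' Branches are flat: nested parentheses are rejected, since none occur in
#' the worked placements this notation was transcribed from.
#'
#' @param notation a placement string
#' @return a `ring_path`: list with `main` (character vector of ring
#'   labels), `branches` (list mapping main index -> list of branch tokens;
#'   each token a list of ring-label character vectors, one vector per
#'   hyphen-linked element, alternatives kept together), and `raw`.
#' @examples
#' p <- parse_placement("A(B)-E(G)-eE-F-L")
#' p$main
#' rings_occupied(p)
#' @export
parse_placement <- function(notation) {
  if (!is.character(notation) || length(notation) != 1L || !nzchar(notation))
    stop("notation must be a non-empty string")
  raw <- notation
  s <- gsub("\\s+", "", sub("^\\s*Rings\\s+", "", notation))
  if (!nzchar(s)) stop("notation must be a non-empty string")

  n <- nchar(s)
  chars <- strsplit(s, "")[[1]]
  perr <- function(i, msg) stop("parse error at character ", i, ": ", msg)

  main <- character(0)
  branches <- list()
  token <- ""          # current main-path element
  just_branched <- FALSE
  i <- 1L
  flush_main <- function() {
    if (!nzchar(token)) perr(i, "empty path segment")
    main <<- c(main, token)
    token <<- ""
  }
  while (i <= n) {
    ch <- chars[i]
    if (ch == "(") {
      if (!nzchar(token) && !just_branched)
        perr(i, "branch with no preceding ring")
      if (nzchar(token)) flush_main()
      depth <- 1L
      j <- i + 1L
      while (j <= n && depth > 0L) {
        if (chars[j] == "(") depth <- depth + 1L
        if (chars[j] == ")") depth <- depth - 1L
        if (depth > 1L) perr(j, "nested parentheses are not supported")
        j <- j + 1L
      }
      if (depth != 0L) perr(i, "unbalanced parentheses")
      inner <- substr(s, i + 1L, j - 2L)
      if (!nzchar(inner)) perr(i, "empty branch")
      idx <- as.character(length(main))
      tok <- .parse_branch_token(inner, i)
      branches[[idx]] <- c(branches[[idx]], list(tok))
      just_branched <- TRUE
      i <- j
    } else if (ch == ")") {
      perr(i, "unbalanced parentheses")
    } else if (ch == "-") {
      if (!just_branched) flush_main()
      just_branched <- FALSE
      i <- i + 1L
    } else {
      token <- paste0(token, ch)
      just_branched <- FALSE
      i <- i + 1L
    }
  }
  if (nzchar(token)) flush_main() else if (!just_branched)
    perr(n, "empty path segment")

  structure(list(main = main, branches = branches, raw = raw),
            class = "ring_path")
}

# a branch token is itself hyphen-linked; each element may carry
# slash-separated alternatives
.parse_branch_token <- function(inner, at) {
  parts <- strsplit(inner, "-", fixed = TRUE)[[1]]
  if (!length(parts) || any(!nzchar(parts)))
    stop("parse error at character ", at, ": empty branch segment")
  lapply(parts, function(p) {
    alts <- strsplit(p, "/", fixed = TRUE)[[1]]
    if (!length(alts) || any(!nzchar(alts)))
      stop("parse error at character ", at, ": empty alternative")
    alts
  })
}

#' Serialize a ring path to canonical notation
#'
#' Canonical form: no whitespace, no `"Rings "` prefix.  `parse_placement`
#' composed with `serialize_placement` is idempotent.
#'
#' @param p a `ring_path`
#' @return the canonical placement string
#' @export
serialize_placement <- function(p) {
  stopifnot(inherits(p, "ring_path"))
  out <- character(0)
  for (i in seq_along(p$main)) {
    seg <- p$main[i]
    idx <- as.character(i)
    if (!is.null(p$branches[[idx]])) {
      for (tok in p$branches[[idx]]) {
        seg <- paste0(seg, "(",
                      paste(vapply(tok, paste, "", collapse = "/"),
                            collapse = "-"), ")")
      }
    }
    out <- c(out, seg)
  }
  paste(out, collapse = "-")
}

#' Rings occupied by a placement path
#'
#' The union of all Ring labels in the main path and every branch;
#' slash alternatives contribute all of their members.
#'
#' @param p a `ring_path`
#' @param t optionally, a `cyp_template` to validate labels against
#' @return character vector of ring labels (unique, in order of first
#'   appearance); alternatives carry the attribute `"alternatives"`.
#' @export
rings_occupied <- function(p, t = NULL) {
  stopifnot(inherits(p, "ring_path"))
  occ <- character(0)
  alt <- character(0)
  for (i in seq_along(p$main)) {
    occ <- c(occ, p$main[i])
    idx <- as.character(i)
    for (tok in p$branches[[idx]] %||% list()) {
      for (el in tok) {
        occ <- c(occ, el)
        if (length(el) > 1L) alt <- c(alt, el)
      }
    }
  }
  occ <- unique(occ)
  if (!is.null(t)) {
    unknown <- setdiff(occ, names(t$rings))
    if (length(unknown))
      stop("placement names unknown ring(s): ",
           paste(unknown, collapse = ", "))
  }
  attr(occ, "alternatives") <- unique(alt)
  occ
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ring_path <- function(x, ...) {
  cat("<ring_path> ", serialize_placement(x), "\n", sep = "")
  invisible(x)
}
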