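#' Select atoms with a small selection language
#'
#' Expressions combine per-atom predicates with \code{and}, \code{or},
#' \code{not} and parentheses.  Predicates:
#' \describe{
#'   \item{\code{name N ...}}{atom name is one of the words given.}
#'   \item{\code{resname R ...}}{residue name matches.}
#'   \item{\code{resid n ...}}{residue number; ranges as \code{a:b}.}
#'   \item{\code{chain C ...}}{chain / domain label.}
#'   \item{\code{element E ...}}{element symbol.}
#'   \item{\code{species S ...}}{species tag, e.g. \code{water-oxygen},
#'     \code{cation}.}
#'   \item{\code{index i ...}}{1-based atom index; ranges allowed.}
#'   \item{\code{all}, \code{none}}{everything / nothing.}
#' }
#' Matching is case-insensitive for names.  The result is a sorted integer
#' index vector; an empty selection is legal.
#'
#' @param traj a \linkS4class{Trajectory} (or a topology data.frame).
#' @param expression selection string, e.g.
#'   \code{"resid 653 and name CG"}, \code{"species cation or species anion"}.
#' @return sorted integer vector of atom indices.
#' @examples
#' ## given a trajectory `tr`:
#' ## selectAtoms(tr, "resname ASN and not element H")
#' @export
selectAtoms <- function(traj, expression) {
  top <- if (is(traj, "Trajectory")) traj@topology else traj
  toks <- .sel_tokenize(expression)
  st <- new.env(parent = emptyenv())
  st$toks <- toks; st$pos <- 1L; st$expr <- expression
  mask <- .sel_or(st, top)
  if (st$pos <= nrow(st$toks))
    .sel_err(st, sprintf("unexpected token '%s'", st$toks$text[st$pos]))
  which(mask)
}

.sel_keywords <- c("and", "or", "not", "(", ")",
                   "name", "resname", "resid", "chain", "element",
                   "species", "index", "all", "none")

.sel_tokenize <- function(expr) {
  pat <- "\\(|\\)|[^()\\s]+"
  m <- gregexpr(pat, expr, perl = TRUE)[[1]]
  if (m[1] == -1) return(data.frame(text = character(), at = integer()))
  data.frame(text = regmatches(expr, gregexpr(pat, expr, perl = TRUE))[[1]],
             at = as.integer(m), stringsAsFactors = FALSE)
}

.sel_err <- function(st, msg) {
  at <- if (st$pos <= nrow(st$toks)) st$toks$at[st$pos] else nchar(st$expr) + 1L
  stop(sprintf("selection parse error at position %d: %s\n  in: %s",
               at, msg, st$expr), call. = FALSE)
}

.sel_peek <- function(st) if (st$pos <= nrow(st$toks)) st$toks$text[st$pos] else NA_character_

.sel_or <- function(st, top) {
  m <- .sel_and(st, top)
  while (identical(tolower(.sel_peek(st)), "or")) {
    st$pos <- st$pos + 1L
    m <- m | .sel_and(st, top)
  }
  m
}

.sel_and <- function(st, top) {
  m <- .sel_unary(st, top)
  while (identical(tolower(.sel_peek(st)), "and")) {
    st$pos <- st$pos + 1L
    m <- m & .sel_unary(st, top)
  }
  m
}

.sel_unary <- function(st, top) {
  tk <- .sel_peek(st)
  if (is.na(tk)) .sel_err(st, "expected a predicate")
  low <- tolower(tk)
  if (low == "not") {
    st$pos <- st$pos + 1L
    return(!.sel_unary(st, top))
  }
  if (tk == "(") {
    st$pos <- st$pos + 1L
    m <- .sel_or(st, top)
    if (!identical(.sel_peek(st), ")")) .sel_err(st, "expected ')'")
    st$pos <- st$pos + 1L
    return(m)
  }
  .sel_predicate(st, top)
}

.sel_values <- function(st) {
  vals <- character()
  repeat {
    tk <- .sel_peek(st)
    if (is.na(tk) || tolower(tk) %in% .sel_keywords) break
    vals <- c(vals, tk); st$pos <- st$pos + 1L
  }
  if (!length(vals)) .sel_err(st, "predicate needs at least one value")
  vals
}

.sel_numbers <- function(st) {
  vals <- integer()
  got <- FALSE
  repeat {
    tk <- .sel_peek(st)
    if (is.na(tk) || tolower(tk) %in% .sel_keywords) break
    if (grepl("^-?[0-9]+:-?[0-9]+$", tk)) {
      ab <- as.integer(strsplit(tk, ":", fixed = TRUE)[[1]])
      vals <- c(vals, seq(ab[1], ab[2]))
    } else if (grepl("^-?[0-9]+$", tk)) {
      vals <- c(vals, as.integer(tk))
    } else .sel_err(st, sprintf("expected a number or a:b range, got '%s'", tk))
    got <- TRUE; st$pos <- st$pos + 1L
  }
  if (!got) .sel_err(st, "predicate needs at least one number")
  vals
}

.sel_predicate <- function(st, top) {
  kw <- tolower(.sel_peek(st))
  st$pos <- st$pos + 1L
  n <- nrow(top)
  switch(kw,
    all = rep(TRUE, n),
    none = rep(FALSE, n),
    name = toupper(top$name) %in% toupper(.sel_values(st)),
    resname = toupper(top$resname) %in% toupper(.sel_values(st)),
    chain = toupper(top$chain) %in% toupper(.sel_values(st)),
    element = toupper(top$element) %in% toupper(.sel_values(st)),
    species = tolower(top$species) %in% tolower(.sel_values(st)),
    resid = top$resid %in% .sel_numbers(st),
    index = seq_len(n) %in% .sel_numbers(st),
    { st$pos <- st$pos - 1L
      .sel_err(st, sprintf("unknown predicate '%s'", .sel_peek(st))) }
  )
}
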