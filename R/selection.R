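#' Atom selection mini-language
#'
#' Selections are strings over the predicates `chain <id[,id...]>`,
#' `resid <a[-b][,c-d...]>`, `resname <name[,name...]>`,
#' `name <atom[,atom...]>`, the atom-class keywords `heavy` (element not
#' H/D), `mainchain` (atom names N, CA, C, O), `polar` (element N or O),
#' `hydrophobic` (element C), `water` (resname HOH/WAT), `protein`
#' (non-water), and `all`, combined with `and`, `or`, `not` and
#' parentheses. Multi-valued arguments are comma separated with no spaces:
#' `"chain C and resid 771-803 and heavy"`.
#'
#' @param structure A [structure3d] (or the topology of a [trajectory]).
#' @param expression Selection string.
#' @return Sorted integer vector of atom indices (possibly empty).
#' @export
select_atoms <- function(structure, expression) {
  if (inherits(structure, "trajectory")) structure <- structure$topology
  stopifnot(inherits(structure, "structure3d"))
  atoms <- structure$atoms
  toks <- strsplit(trimws(gsub("([()])", " \\1 ", expression)), "\\s+")[[1]]
  toks <- toks[toks != ""]
  if (!length(toks)) stop("selection-syntax error: empty expression")
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  take <- function() { t <- peek(); pos <<- pos + 1L; t }
  mask_kw <- function(kw) switch(kw,
    heavy = !(atoms$element %in% c("H", "D")),
    mainchain = atoms$name %in% c("N", "CA", "C", "O"),
    polar = atoms$element %in% c("N", "O"),
    hydrophobic = atoms$element == "C",
    water = atoms$resname %in% c("HOH", "WAT"),
    protein = !(atoms$resname %in% c("HOH", "WAT")),
    all = rep(TRUE, nrow(atoms)),
    NULL)
  parse_resid <- function(arg) {
    parts <- strsplit(arg, ",", fixed = TRUE)[[1]]
    keep <- rep(FALSE, nrow(atoms))
    for (p in parts) {
      if (grepl("^-?\\d+--?\\d+$", p) && grepl("-", substr(p, 2, nchar(p)))) {
        sp <- regexpr("-", substr(p, 2, nchar(p))) + 1L
        a <- as.integer(substr(p, 1, sp - 1)); b <- as.integer(substr(p, sp + 1, nchar(p)))
        if (is.na(a) || is.na(b) || a > b)
          stop("selection-syntax error: bad residue range '", p, "'")
        keep <- keep | (atoms$resid >= a & atoms$resid <= b)
      } else if (grepl("^-?\\d+$", p)) {
        keep <- keep | atoms$resid == as.integer(p)
      } else stop("selection-syntax error: bad residue range '", p, "'")
    }
    keep
  }
  primitive <- function() {
    t <- take()
    if (is.na(t)) stop("selection-syntax error: unexpected end of expression")
    if (t == "(") {
      m <- expr()
      if (!identical(take(), ")"))
        stop("selection-syntax error: unbalanced parenthesis")
      return(m)
    }
    if (t == "not") return(!primitive())
    kw <- mask_kw(t)
    if (!is.null(kw)) return(kw)
    arg <- take()
    if (is.na(arg))
      stop("selection-syntax error: '", t, "' needs an argument")
    switch(t,
      chain = atoms$chain %in% strsplit(arg, ",", fixed = TRUE)[[1]],
      resid = parse_resid(arg),
      resname = atoms$resname %in% strsplit(arg, ",", fixed = TRUE)[[1]],
      name = atoms$name %in% strsplit(arg, ",", fixed = TRUE)[[1]],
      stop("selection-syntax error: unknown keyword '", t, "'"))
  }
  term <- function() {
    m <- primitive()
    while (identical(peek(), "and")) { take(); m <- m & primitive() }
    m
  }
  expr <- function() {
    m <- term()
    while (identical(peek(), "or")) { take(); m <- m | term() }
    m
  }
  m <- expr()
  if (pos <= length(toks))
    stop("selection-syntax error: trailing tokens from '", peek(), "'")
  which(m)
}

# Residue keys (chain:resid:resname) for a set of atom indices.
.residue_keys <- function(atoms, idx) {
  paste(atoms$chain[idx], atoms$resid[idx], atoms$resname[idx], sep = ":")
}
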