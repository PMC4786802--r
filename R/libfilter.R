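#' Parse a compound library from SMILES or SDF
#'
#' `.smi`/`.smiles` files hold one `SMILES<TAB>id` record per line (a
#' missing id becomes `mol<n>`); `.sdf` files are V2000 SD files whose
#' title line is the id. Unparsable records are skipped with a message,
#' never fatal; a library with zero parsable records is an error.
#'
#' @param path Library file path.
#' @param format "auto" (by extension), "smiles" or "sdf".
#' @return A `compound_library` data.frame with columns `id`, `smiles`,
#'   `cansmi` (OpenBabel canonical SMILES); attribute `n_skipped`.
#' @export
parse_library <- function(path, format = c("auto", "smiles", "sdf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto")
    format <- if (grepl("\\.sdf$", path, ignore.case = TRUE)) "sdf"
              else "smiles"
  if (format == "sdf") {
    sdf <- ChemmineR::read.SDFset(path)
    ids <- vapply(seq_along(sdf), function(i)
      ChemmineR::header(sdf[[i]])[["Molecule_Name"]], "")
    ids[!nzchar(ids)] <- paste0("mol", which(!nzchar(ids)))
    smi <- as.character(ChemmineR::sdf2smiles(sdf))
    recs <- data.frame(id = ids, smiles = smi)
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(lines, "[\t ]+")
    recs <- data.frame(
      smiles = vapply(parts, `[`, "", 1),
      id = vapply(seq_along(parts), function(i)
        if (length(parts[[i]]) > 1) parts[[i]][2] else paste0("mol", i), ""))
  }
  can <- vapply(recs$smiles, .canonical_smiles, "", USE.NAMES = FALSE)
  bad <- which(is.na(can))
  if (length(bad)) {
    message(sprintf("skipped %d unparsable record(s): %s", length(bad),
                    paste(recs$id[bad], collapse = ", ")))
    recs <- recs[-bad, , drop = FALSE]
    can <- can[-bad]
  }
  if (!nrow(recs)) stop("empty-library error: no parsable records in ", path)
  out <- data.frame(id = recs$id, smiles = recs$smiles, cansmi = can,
                    row.names = NULL)
  attr(out, "n_skipped") <- length(bad)
  class(out) <- c("compound_library", "data.frame")
  out
}

.canonical_smiles <- function(smi) {
  out <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN",
                                               paste0(smi, "\n"))),
    error = function(e) "")
  out <- trimws(strsplit(out, "[\t\n]")[[1]][1])
  if (is.na(out) || !nzchar(out)) NA_character_ else out
}

.library_sdf <- function(lib, add_h = FALSE) {
  src <- paste0(paste(lib$smiles, lib$id, sep = "\t"), "\n", collapse = "")
  opts <- if (add_h) data.frame(names = c("h", "gen2D"), args = c("", ""))
          else data.frame(names = "gen2D", args = "")
  str <- ChemmineOB::convertFormat("SMI", "SDF", src, options = opts)
  ChemmineR::read.SDFset(ChemmineR::read.SDFstr(strsplit(str, "\n")[[1]]))
}

# SMARTS used for descriptor counting. Rotatable bonds: non-ring single
# bonds between non-terminal heavy atoms, excluding triple-bond ends and
# amide C-N bonds.
.smarts_rotatable <- "[!$(*#*)&!D1]-&!@[!$(*#*)&!D1]"
.smarts_amide_cn <- "[CX3](=[OX1])-&!@[NX3&!D1]"
.smarts_aromatic_rings <- c("a1aaaa1", "a1aaaaa1", "a1aaaaaa1")

# Net formal charge from the bracket atoms of a SMILES string.
.smiles_net_charge <- function(smi) {
  br <- regmatches(smi, gregexpr("\\[[^]]*\\]", smi))[[1]]
  if (!length(br)) return(0L)
  total <- 0L
  for (b in br) {
    ch <- regmatches(b, gregexpr("[+-][0-9]*", b))[[1]]
    for (c in ch) {
      n <- suppressWarnings(as.integer(substr(c, 2, nchar(c))))
      total <- total + (if (substr(c, 1, 1) == "+") 1L else -1L) *
        (if (is.na(n)) 1L else n)
    }
  }
  total
}

#' Filterable molecular descriptors
#'
#' The eight drug-likeness properties the filter cascade acts on:
#' molecular weight (average atomic weights, Da), Crippen-style atomic
#' contribution cLogP, Ertl topological polar surface area (A^2),
#' H-bond donors (N/O bearing hydrogen), H-bond acceptors (Lipinski N+O
#' count), rotatable bonds (non-ring single bonds between non-terminal
#' heavy atoms, amide C-N excluded), net formal charge, aromatic ring
#' count and the Solubility Forecast Index SFI = cLogP + aromatic rings.
#'
#' @param lib A `compound_library` from [parse_library()], or a character
#'   vector of SMILES.
#' @return data.frame: id, mw, clogp, n_aromatic_rings, sfi, tpsa, hbd,
#'   hba, rotb, net_charge.
#' @export
mol_descriptors <- function(lib) {
  lib <- .as_library(lib)
  sdf <- .library_sdf(lib)
  props <- ChemmineR::propOB(sdf)
  rot <- ChemmineR::smartsSearchOB(sdf, .smarts_rotatable,
                                   uniqueMatches = TRUE)
  ami <- ChemmineR::smartsSearchOB(sdf, .smarts_amide_cn,
                                   uniqueMatches = TRUE)
  nar <- Reduce(`+`, lapply(.smarts_aromatic_rings, function(s)
    ChemmineR::smartsSearchOB(sdf, s, uniqueMatches = TRUE)))
  # Lipinski-style acceptor count: plain N+O atom tally
  nno <- ChemmineR::smartsSearchOB(sdf, "[#7,#8]", uniqueMatches = TRUE)
  chg <- vapply(lib$cansmi, .smiles_net_charge, 0L, USE.NAMES = FALSE)
  out <- data.frame(
    id = lib$id,
    mw = props$MW,
    clogp = props$logP,
    n_aromatic_rings = as.integer(nar),
    sfi = props$logP + as.integer(nar),
    tpsa = props$TPSA,
    hbd = as.integer(props$HBD),
    hba = as.integer(nno),
    rotb = as.integer(rot - ami),
    net_charge = chg,
    row.names = NULL)
  out
}

.as_library <- function(lib) {
  if (inherits(lib, "compound_library")) return(lib)
  if (is.character(lib)) {
    ids <- names(lib) %||% paste0("mol", seq_along(lib))
    can <- vapply(lib, .canonical_smiles, "", USE.NAMES = FALSE)
    if (anyNA(can)) stop("unparsable SMILES: ",
                         paste(lib[is.na(can)], collapse = ", "))
    out <- data.frame(id = ids, smiles = unname(lib), cansmi = can)
    class(out) <- c("compound_library", "data.frame")
    return(out)
  }
  stop("expected a compound_library or character SMILES vector")
}

#' Monoisotopic mass of a molecular formula
#'
#' Sum of most-abundant-isotope atomic masses, the arithmetic behind
#' "calcd" electrospray HRMS values. Pass `adduct = "H"` (and charge 1)
#' to obtain an [M+H]+ value from a neutral formula, or include the
#' adduct hydrogen in the formula itself.
#'
#' @param formula Formula string ("C25H37N4O9") or named count vector
#'   (`c(C = 25, H = 37, ...)`).
#' @param adduct Optional formula added on top (e.g. "H", "Na").
#' @return Mass in Da (full double precision; report to 4 decimals as is
#'   conventional for HRMS).
#' @export
monoisotopic_mass <- function(formula, adduct = NULL) {
  counts <- if (is.character(formula)) .parse_formula(formula)
            else formula
  if (!length(counts)) return(0)
  if (any(counts < 0)) stop("formula error: negative element count")
  m <- .monoisotopic_masses[names(counts)]
  if (anyNA(m))
    stop("formula error: unknown element symbol ",
         paste(names(counts)[is.na(m)], collapse = ", "))
  total <- sum(m * counts)
  if (!is.null(adduct)) total <- total + monoisotopic_mass(adduct)
  total
}

.parse_formula <- function(f) {
  f <- gsub("\\s", "", f)
  if (!nzchar(f)) return(numeric(0))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", f)[[1]]
  toks <- regmatches(f, list(m))[[1]]
  if (sum(nchar(toks)) != nchar(f))
    stop("formula error: cannot parse '", f, "'")
  el <- sub("[0-9]*$", "", toks)
  n <- as.numeric(ifelse(grepl("[0-9]$", toks),
                         sub("^[A-Za-z]+", "", toks), "1"))
  tapply(n, el, sum)
}

#' Remove duplicate structures from a library
#'
#' Uniqueness is judged on the OpenBabel canonical SMILES, so different
#' spellings of one structure collapse; the first occurrence is kept.
#'
#' @param lib A `compound_library`.
#' @return List with `unique` (a `compound_library`) and `duplicates`
#'   (data.frame id, duplicate_of).
#' @export
dedup_library <- function(lib) {
  lib <- .as_library(lib)
  dup <- duplicated(lib$cansmi)
  first_of <- lib$id[match(lib$cansmi, lib$cansmi)]
  uni <- lib[!dup, , drop = FALSE]
  rownames(uni) <- NULL
  class(uni) <- c("compound_library", "data.frame")
  list(unique = uni,
       duplicates = data.frame(id = lib$id[dup],
                               duplicate_of = first_of[dup]))
}

#' Drug-likeness filter policy
#'
#' Descriptor bounds (defaults: molecular weight < 450 Da; cLogP and SFI
#' both in [-3, 1]; TPSA < 110 A^2; H-bond donors and acceptors in
#' [0, 5]; rotatable bonds in [0, 6]; net formal charge in [-1, 1])
#' plus PAINS and reactive-group substructure pattern lists. "<" bounds
#' are strict, "between" bounds closed, matching the usual statement of
#' these rules; every bound is configurable.
#'
#' @param mw_max,tpsa_max Strict upper bounds.
#' @param clogp,sfi,hbd,hba,rotb,net_charge Closed intervals c(lo, hi).
#' @param pains Pattern table (data.frame smarts, id) or NULL to disable;
#'   default: the packaged published PAINS A/B/C SMARTS.
#' @param reactive Pattern table for reactive/warhead groups or NULL;
#'   default: the packaged minimal list.
#' @return A `filter_policy` list.
#' @export
filter_policy <- function(mw_max = 450, clogp = c(-3, 1), sfi = c(-3, 1),
                          tpsa_max = 110, hbd = c(0, 5), hba = c(0, 5),
                          rotb = c(0, 6), net_charge = c(-1, 1),
                          pains = pains_patterns(),
                          reactive = reactive_patterns()) {
  structure(list(mw_max = mw_max, clogp = clogp, sfi = sfi,
                 tpsa_max = tpsa_max, hbd = hbd, hba = hba, rotb = rotb,
                 net_charge = net_charge, pains = pains,
                 reactive = reactive),
            class = "filter_policy")
}

#' Packaged substructure pattern tables
#'
#' `pains_patterns()` returns the published pan-assay interference (PAINS)
#' SMARTS, families A/B/C, as shipped in `extdata/pains_abc_v1.tsv`;
#' `reactive_patterns()` a minimal curated list of reactive/warhead
#' groups. Both are plain TSV (columns `smarts`, `id`, `family`) and can
#' be swapped for any other pattern table of the same shape.
#'
#' @param path Optional path to an alternative pattern TSV.
#' @return data.frame with columns smarts, id, family.
#' @export
pains_patterns <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "pains_abc_v1.tsv", package = "rcscreen")
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname pains_patterns
#' @export
reactive_patterns <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "reactive_v1.tsv", package = "rcscreen")
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Match substructure patterns against a library
#'
#' @param lib A `compound_library` or SMILES vector.
#' @param patterns data.frame with a `smarts` and an `id` column.
#' @return Logical matrix (molecules x patterns).
#' @export
match_patterns <- function(lib, patterns) {
  lib <- .as_library(lib)
  sdf <- .library_sdf(lib, add_h = TRUE)  # patterns use explicit H atoms
  hits <- vapply(seq_len(nrow(patterns)), function(i)
    ChemmineR::smartsSearchOB(sdf, patterns$smarts[i],
                              uniqueMatches = TRUE) > 0,
    logical(nrow(lib)))
  hits <- matrix(hits, nrow = nrow(lib),
                 dimnames = list(lib$id, patterns$id))
  hits
}

#' Apply the drug-likeness filter cascade with a full audit
#'
#' A molecule passes iff every descriptor bound holds and it matches no
#' PAINS or reactive pattern. The audit records every violated rule per
#' molecule (not only the first), per-rule rejection counts, and totals;
#' because each rule is evaluated independently, the audit is invariant
#' to rule order.
#'
#' @param lib A `compound_library` or SMILES vector.
#' @param policy A [filter_policy()].
#' @param descriptors Optional precomputed [mol_descriptors()] table.
#' @return A `filter_audit` list: `molecules` (id, pass, violated_rules,
#'   all descriptors), `rule_counts` (rejections per rule), `n_pass`,
#'   `n_total`.
#' @export
apply_filters <- function(lib, policy = filter_policy(),
                          descriptors = NULL) {
  lib <- .as_library(lib)
  d <- descriptors %||% mol_descriptors(lib)
  viol <- list(
    "mw<450"      = !(d$mw < policy$mw_max),
    "clogp_-3_1"  = !(d$clogp >= policy$clogp[1] & d$clogp <= policy$clogp[2]),
    "sfi_-3_1"    = !(d$sfi >= policy$sfi[1] & d$sfi <= policy$sfi[2]),
    "tpsa<110"    = !(d$tpsa < policy$tpsa_max),
    "hbd_0_5"     = !(d$hbd >= policy$hbd[1] & d$hbd <= policy$hbd[2]),
    "hba_0_5"     = !(d$hba >= policy$hba[1] & d$hba <= policy$hba[2]),
    "rotb_0_6"    = !(d$rotb >= policy$rotb[1] & d$rotb <= policy$rotb[2]),
    "charge_-1_1" = !(d$net_charge >= policy$net_charge[1] &
                      d$net_charge <= policy$net_charge[2]))
  names(viol)[1] <- sprintf("mw<%g", policy$mw_max)
  names(viol)[4] <- sprintf("tpsa<%g", policy$tpsa_max)
  if (!is.null(policy$pains) && nrow(policy$pains))
    viol$pains <- rowSums(match_patterns(lib, policy$pains)) > 0
  if (!is.null(policy$reactive) && nrow(policy$reactive))
    viol$reactive <- rowSums(match_patterns(lib, policy$reactive)) > 0
  vm <- do.call(cbind, viol)
  violated <- apply(vm, 1, function(r)
    paste(colnames(vm)[r], collapse = ","))
  mols <- cbind(data.frame(id = lib$id, pass = !apply(vm, 1, any),
                           violated_rules = violated), d[-1])
  out <- list(molecules = mols,
              rule_counts = colSums(vm),
              n_pass = sum(mols$pass), n_total = nrow(mols))
  class(out) <- "filter_audit"
  out
}

#' @export
print.filter_audit <- function(x, ...) {
  cat(sprintf("filter_audit: %d / %d pass\n", x$n_pass, x$n_total))
  print(x$rule_counts)
  invisible(x)
}

#' Write a filter audit to disk
#'
#' @param audit A `filter_audit`.
#' @param tsv Path for the per-molecule audit TSV.
#' @param json Optional path for the JSON summary (totals + rule counts).
#' @param pass_smi Optional path for a pass-list SMILES file.
#' @param lib The audited library (needed for `pass_smi`).
#' @return Invisibly, `tsv`.
#' @export
write_filter_audit <- function(audit, tsv, json = NULL, pass_smi = NULL,
                               lib = NULL) {
  utils::write.table(audit$molecules, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(json))
    jsonlite::write_json(
      list(n_total = audit$n_total, n_pass = audit$n_pass,
           rule_counts = as.list(audit$rule_counts)),
      json, auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(pass_smi)) {
    stopifnot(!is.null(lib))
    keep <- lib$id %in% audit$molecules$id[audit$molecules$pass]
    writeLines(paste(lib$smiles[keep], lib$id[keep], sep = "\t"), pass_smi)
  }
  invisible(tsv)
}
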