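## Compound-table layer: SMILES validation/canonicalization, the labeled
## dataset container, and CSV / .smi / SDF readers and writers.
##
## Labels follow the three-kingdom scheme used throughout the package:
## 0 = Animalia, 1 = Bacteria, 2 = Fungi.

KINGDOM_LABELS <- c(`0` = "Animalia", `1` = "Bacteria", `2` = "Fungi")

.ELEMENTS <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
  "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe",
  "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr",
  "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe", "Cs", "Ba", "W", "Pt", "Au", "Hg", "Tl", "Pb", "Bi")

## Tokenize a SMILES string; returns a character vector of tokens or NULL if
## an illegal character sequence is hit. Organic-subset atoms, bracket atoms,
## bonds, branches, ring-bond digits and dots are recognised.
smiles_tokens <- function(s) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(chars)
  toks <- character(0)
  i <- 1
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1
      if (j > n) return(NULL)                      # unterminated bracket atom
      toks <- c(toks, paste(chars[i:j], collapse = ""))
      i <- j + 1
    } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
      two <- if (i < n) paste0(ch, chars[i + 1]) else ""
      if (two %in% c("Cl", "Br")) {
        toks <- c(toks, two); i <- i + 2
      } else {
        toks <- c(toks, ch); i <- i + 1
      }
    } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
      toks <- c(toks, ch); i <- i + 1
    } else if (ch == "%") {
      if (i + 2 > n || !grepl("^[0-9]{2}$", paste0(chars[i + 1], chars[i + 2])))
        return(NULL)
      toks <- c(toks, paste0("%", chars[i + 1], chars[i + 2])); i <- i + 3
    } else if (grepl("[0-9]", ch) || ch %in% c("-", "=", "#", "$", ":", "/", "\\", "(", ")", ".")) {
      toks <- c(toks, ch); i <- i + 1
    } else {
      return(NULL)
    }
  }
  toks
}

.is_atom_token <- function(tok) {
  grepl("^\\[", tok) ||
    tok %in% c("B", "C", "N", "O", "P", "S", "F", "I", "Cl", "Br",
               "b", "c", "n", "o", "p", "s")
}

.bracket_ok <- function(tok) {
  body <- sub("^\\[", "", sub("\\]$", "", tok))
  m <- regmatches(body, regexec(
    "^([0-9]*)([A-Z][a-z]?|se|as|te|si|[bcnops]|\\*)(@@?|@(TH|AL|SP|TB|OH)[0-9]+)?(H[0-9]*)?([+-][0-9]*|\\++|-+)?(:[0-9]+)?$",
    body))[[1]]
  if (length(m) == 0) return(FALSE)
  el <- m[3]
  el %in% c("*", "b", "c", "n", "o", "p", "s", "se", "as", "te", "si") ||
    el %in% .ELEMENTS
}

#' Check SMILES syntax
#'
#' Validates bracket atoms, balanced branches and paired ring-bond closures.
#' This guards the structured parse-error contract: the underlying OpenBabel
#' reader is lenient and will silently truncate malformed input such as
#' `"C("`.
#'
#' @param smiles character vector of SMILES strings.
#' @return logical vector, `TRUE` where the string is syntactically valid.
#' @export
smiles_is_valid <- function(smiles) {
  vapply(smiles, function(s) {
    if (is.na(s) || !nzchar(s)) return(FALSE)
    toks <- smiles_tokens(s)
    if (is.null(toks) || length(toks) == 0) return(FALSE)
    depth <- 0
    rings <- character(0)
    seen_atom <- FALSE
    prev <- ""
    for (tok in toks) {
      if (.is_atom_token(tok)) {
        if (grepl("^\\[", tok) && !.bracket_ok(tok)) return(FALSE)
        seen_atom <- TRUE
      } else if (tok == "(") {
        if (!seen_atom || prev %in% c("-", "=", "#", "$", ":", ".")) return(FALSE)
        depth <- depth + 1
      } else if (tok == ")") {
        depth <- depth - 1
        if (depth < 0) return(FALSE)
        if (prev %in% c("(", "-", "=", "#", "$", ":", ".")) return(FALSE)
      } else if (grepl("^[0-9]$|^%[0-9]{2}$", tok)) {
        if (!seen_atom) return(FALSE)
        key <- sub("^%", "", tok)
        if (key %in% rings) rings <- setdiff(rings, key) else rings <- c(rings, key)
      } else if (tok %in% c("-", "=", "#", "$", ":", "/", "\\")) {
        if (!seen_atom || prev %in% c("-", "=", "#", "$", ":", ".")) return(FALSE)
      } else if (tok == ".") {
        if (!seen_atom || depth > 0) return(FALSE)
      }
      prev <- tok
    }
    depth == 0 && length(rings) == 0 && seen_atom &&
      !prev %in% c("-", "=", "#", "$", ":", "/", "\\", ".")
  }, logical(1), USE.NAMES = FALSE)
}

## heavy-atom count from tokens ([H] and [2H] etc. do not count)
.heavy_atoms <- function(s) {
  toks <- smiles_tokens(s)
  if (is.null(toks)) return(0L)
  sum(vapply(toks, function(t) {
    .is_atom_token(t) && !grepl("^\\[[0-9]*H[0-9]*[+-]?[0-9]*\\]$", t)
  }, logical(1)))
}

.ob_canonical <- function(smiles) {
  ## one OpenBabel call for the whole vector; index tags keep alignment even
  ## if the converter drops a molecule
  inp <- paste(paste(smiles, seq_along(smiles)), collapse = "\n")
  raw <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", inp)),
    error = function(e) "")
  out <- rep(NA_character_, length(smiles))
  lines <- strsplit(raw, "\n", fixed = TRUE)[[1]]
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "[\t ]+")[[1]]
    if (length(parts) >= 2) {
      idx <- suppressWarnings(as.integer(parts[length(parts)]))
      if (!is.na(idx) && idx >= 1 && idx <= length(smiles))
        out[idx] <- parts[1]
    }
  }
  out
}

#' Canonicalize SMILES strings
#'
#' Maps every syntactically valid writing of a molecule to one canonical
#' SMILES (OpenBabel canonical order), so that "same molecule, different
#' SMILES" collapses to a single record. Multi-fragment inputs (salts) are
#' reduced to the largest covalent fragment; stereo descriptors are preserved
#' as written. The map is idempotent: canonical input returns itself.
#'
#' @param smiles character vector of SMILES strings.
#' @param strict if `TRUE` (default), unparseable input raises an error
#'   naming the offending string; if `FALSE`, it yields `NA`.
#' @return character vector of canonical SMILES (with `NA` for failures when
#'   `strict = FALSE`).
#' @export
canonicalize_smiles <- function(smiles, strict = TRUE) {
  stopifnot(is.character(smiles))
  if (length(smiles) == 0) return(character(0))
  ok <- smiles_is_valid(smiles)
  if (any(!ok) && strict)
    stop("unparseable SMILES: ",
         paste(sQuote(smiles[!ok][seq_len(min(5, sum(!ok)))]), collapse = ", "),
         call. = FALSE)
  out <- rep(NA_character_, length(smiles))
  if (any(ok)) {
    can <- .ob_canonical(smiles[ok])
    ## salts: keep the largest covalent fragment, then re-canonicalize it
    multi <- !is.na(can) & grepl(".", can, fixed = TRUE)
    if (any(multi)) {
      biggest <- vapply(strsplit(can[multi], ".", fixed = TRUE), function(fr) {
        fr[which.max(vapply(fr, .heavy_atoms, numeric(1)))]
      }, character(1))
      can[multi] <- .ob_canonical(biggest)
    }
    out[ok] <- can
  }
  bad <- is.na(out)
  if (any(bad) && strict)
    stop("unparseable SMILES: ",
         paste(sQuote(smiles[bad][seq_len(min(5, sum(bad)))]), collapse = ", "),
         call. = FALSE)
  out
}

#' Construct a labeled compound dataset
#'
#' The central data container: one row per compound with a unique id, a
#' canonical SMILES and a kingdom label (0 = Animalia, 1 = Bacteria,
#' 2 = Fungi). Optional columns carry a free-text taxonomic lineage, a
#' provenance tag, and — for synthetic data — the generator's true label.
#'
#' @param id character vector of unique compound ids.
#' @param smiles character vector of SMILES strings.
#' @param label integer vector with values in `{0, 1, 2}`.
#' @param taxon,source optional character vectors (recycled if length 1).
#' @param true_label optional integer vector of ground-truth labels
#'   (defaults to `label`).
#' @param canonicalize canonicalize SMILES on construction (default `TRUE`).
#' @param strict if `TRUE`, invalid structures raise an error; if `FALSE`
#'   (default), they are dropped with a message giving the dropped count.
#' @return an object of class `"mnp_dataset"`: a list with a `records`
#'   data frame.
#' @export
mnp_dataset <- function(id, smiles, label, taxon = NA_character_,
                        source = NA_character_, true_label = NULL,
                        canonicalize = TRUE, strict = FALSE) {
  id <- as.character(id)
  smiles <- as.character(smiles)
  label <- as.integer(label)
  stopifnot(length(id) == length(smiles), length(id) == length(label))
  if (anyDuplicated(id))
    stop("duplicate compound ids: ",
         paste(unique(id[duplicated(id)])[1:min(5, sum(duplicated(id)))],
               collapse = ", "), call. = FALSE)
  if (length(label) && any(!label %in% 0:2))
    stop("labels must be in {0, 1, 2}; offending ids: ",
         paste(head(id[!label %in% 0:2], 5), collapse = ", "), call. = FALSE)
  true_label <- as.integer(true_label %||% label)
  rec <- data.frame(id = id, smiles = smiles, label = label,
                    taxon = rep_len(as.character(taxon), length(id)),
                    source = rep_len(as.character(source), length(id)),
                    true_label = true_label,
                    stringsAsFactors = FALSE)
  if (canonicalize && nrow(rec)) {
    can <- canonicalize_smiles(rec$smiles, strict = strict)
    drop <- is.na(can)
    if (any(drop)) {
      message(sum(drop), " record(s) with invalid structures dropped")
      rec <- rec[!drop, , drop = FALSE]
      can <- can[!drop]
    }
    rec$smiles <- can
    rownames(rec) <- NULL
  }
  structure(list(records = rec), class = "mnp_dataset")
}

#' @export
length.mnp_dataset <- function(x) nrow(x$records)

#' Subset a dataset
#'
#' @param x an `mnp_dataset`.
#' @param i integer/logical index or character vector of compound ids.
#' @param ... ignored.
#' @return an `mnp_dataset` with the selected records.
#' @export
`[.mnp_dataset` <- function(x, i, ...) {
  if (is.character(i)) {
    j <- match(i, x$records$id)
    if (anyNA(j)) stop("unknown compound id(s): ",
                       paste(head(i[is.na(j)], 5), collapse = ", "))
    i <- j
  }
  rec <- x$records[i, , drop = FALSE]
  rownames(rec) <- NULL
  structure(list(records = rec), class = "mnp_dataset")
}

#' @export
as.data.frame.mnp_dataset <- function(x, ...) x$records

#' @export
print.mnp_dataset <- function(x, ...) {
  cc <- class_counts(x)
  cat("<mnp_dataset> ", length(x), " compounds (",
      paste(sprintf("%s: %d", KINGDOM_LABELS, cc), collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

#' Per-kingdom record counts
#'
#' @param ds an `mnp_dataset`.
#' @return named integer vector with keys `"0"`, `"1"`, `"2"`; always all
#'   three keys, zero where a class is absent, summing to `length(ds)`.
#' @export
class_counts <- function(ds) {
  stopifnot(inherits(ds, "mnp_dataset"))
  tab <- table(factor(ds$records$label, levels = 0:2))
  setNames(as.integer(tab), names(tab))
}

#' Read a compound table
#'
#' Supported formats: CSV with columns `id, smiles, label` (optional `taxon`,
#' `source`), `.smi` files of `SMILES<TAB>id` lines with labels supplied via
#' a sidecar CSV (`id, label`), and SDF with id and label taken from named
#' data fields. All structures are canonicalized; invalid structures are
#' dropped with a message, or raise an error in strict mode.
#'
#' @param path file to read.
#' @param format one of `"csv"`, `"smi"`, `"sdf"`; inferred from the file
#'   extension when omitted.
#' @param strict raise instead of dropping invalid structures.
#' @param labels path of the sidecar label CSV (required for `"smi"`).
#' @param id_field,label_field SDF data-field names (defaults `"id"`,
#'   `"label"`).
#' @return an [mnp_dataset].
#' @export
load_dataset <- function(path, format = c("auto", "csv", "smi", "sdf"),
                         strict = FALSE, labels = NULL,
                         id_field = "id", label_field = "label") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "auto")
    format <- switch(tolower(tools::file_ext(path)),
                     csv = "csv", smi = "smi", sdf = "sdf",
                     stop("cannot infer format from extension: ", path))
  if (format == "csv") {
    df <- read.csv(path, stringsAsFactors = FALSE)
    need <- c("id", "smiles", "label")
    if (!all(need %in% names(df)))
      stop("CSV must have columns id, smiles, label; missing: ",
           paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
    mnp_dataset(df$id, df$smiles, df$label,
                taxon = if ("taxon" %in% names(df)) df$taxon else NA,
                source = if ("source" %in% names(df)) df$source else NA,
                true_label = if ("true_label" %in% names(df)) df$true_label else NULL,
                strict = strict)
  } else if (format == "smi") {
    if (is.null(labels))
      stop(".smi input needs a sidecar label CSV via `labels=`", call. = FALSE)
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(lines, "[\t ]+")
    smi <- vapply(parts, `[`, character(1), 1)
    ids <- vapply(parts, function(p) if (length(p) > 1) p[2] else NA_character_,
                  character(1))
    if (anyNA(ids)) stop(".smi lines must be 'SMILES<TAB>id'", call. = FALSE)
    lab <- read.csv(labels, stringsAsFactors = FALSE)
    j <- match(ids, as.character(lab$id))
    if (anyNA(j)) stop("sidecar CSV misses label(s) for: ",
                       paste(head(ids[is.na(j)], 5), collapse = ", "), call. = FALSE)
    mnp_dataset(ids, smi, lab$label[j], strict = strict)
  } else {
    sdfs <- ChemmineR::read.SDFset(path)
    blocks <- ChemmineR::datablock(sdfs)
    grab <- function(b, f) if (f %in% names(b)) b[[f]] else NA_character_
    ids <- vapply(blocks, grab, character(1), id_field)
    labs <- vapply(blocks, grab, character(1), label_field)
    if (anyNA(ids) || anyNA(labs))
      stop("SDF records must carry '", id_field, "' and '", label_field,
           "' data fields", call. = FALSE)
    smi <- as.character(ChemmineR::sdf2smiles(sdfs))
    mnp_dataset(ids, smi, as.integer(labs), strict = strict)
  }
}

#' Write a compound table to CSV
#'
#' The written file round-trips through [load_dataset]: ids, labels and
#' canonical SMILES are reproduced exactly.
#'
#' @param ds an [mnp_dataset].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "mnp_dataset"))
  write.csv(ds$records, path, row.names = FALSE, na = "")
  invisible(path)
}
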