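## Synthetic compound generator: three structurally separable classes built
## from a closed template grammar (guaranteed-valid SMILES), plus one-way
## microbial -> Animalia label noise emulating symbiosis misannotation.
##
## Class 0 mimics animal-derived chemistry (saturated fused carbocycles with
## alkyl/hydroxyl decoration, steroid-like), class 1 bacterial chemistry
## (aromatic N-heterocycles with amide decoration), class 2 fungal chemistry
## (ester/ketone-rich chains and lactones, polyketide-like).

#' Default template grammar for the synthetic generator
#'
#' Each class is defined by core templates (with one `%s` substitution
#' slot), substituent branches, and optional alkyl prefixes; molecules are
#' assembled as `prefix + sprintf(core, substituent)`, so every product is
#' valid by construction.
#'
#' @return a list with one grammar per class label `"0"`, `"1"`, `"2"`.
#' @export
default_grammar <- function() {
  list(
    `0` = list(  # saturated fused carbocycles, alkyl / hydroxyl decoration
      cores = c("C1CC(%s)C2CCCCC2C1", "C1CCC2CC(%s)CCC2C1",
                "C1CC(%s)C2CCCC2C1", "C1CCC2(CCC(%s)C2)CC1",
                "C1CCC2C(C1)CCC1C2CC(%s)C1", "C1CC2CCC(%s)C2C1",
                "C1CC(%s)CC2CCCCC12"),
      subs = c("C", "CC", "CCC", "CC(C)C", "O", "CO", "CCO", "C(C)O",
               "C(C)C", "CCC(C)C"),
      prefixes = c("", "C", "CC", "CCC", "OC", "CC(C)")
    ),
    `1` = list(  # aromatic N-heterocycles, amide decoration
      cores = c("c1cc(%s)ccn1", "c1cc(%s)cnc1", "c1cnc(%s)nc1",
                "c1ccc2[nH]c(%s)cc2c1", "c1ccc2nc(%s)ccc2c1",
                "c1cn(%s)cn1", "c1csc(%s)n1"),
      subs = c("C(N)=O", "NC(C)=O", "C(=O)NC", "N", "C", "CC", "CN",
               "CC(N)=O", "CNC(C)=O"),
      prefixes = c("", "C", "CC", "NC(=O)", "CN", "CCN")
    ),
    `2` = list(  # ester / ketone chains and lactones
      cores = c("C1CC(%s)CC(=O)O1", "C1C(%s)CC(=O)O1", "C1CC(%s)CCC(=O)O1",
                "CC(=O)OC(%s)CC(C)=O", "CCOC(=O)C(%s)CC(C)=O",
                "COC(=O)C(%s)C(=O)OC", "CC(=O)CC(%s)C(=O)OC"),
      subs = c("C", "CC", "CCC", "OC(C)=O", "C(C)=O", "OC", "CC(C)=O",
               "CC(=O)OC", "CCOC(C)=O"),
      prefixes = c("", "C", "CC", "CC(=O)", "COC(=O)", "CCC")
    )
  )
}

.grammar_cache <- new.env(parent = emptyenv())

## deterministic full enumeration of one class grammar, canonicalized and
## deduplicated; memoized on the grammar content
.enumerate_class <- function(gr) {
  key <- as.character(hash_string(paste(unlist(gr), collapse = "|")))
  if (!is.null(.grammar_cache[[key]])) return(.grammar_cache[[key]])
  combos <- expand.grid(core = gr$cores, sub = gr$subs, prefix = gr$prefixes,
                        stringsAsFactors = FALSE)
  raw <- unique(paste0(combos$prefix, sprintf(combos$core, combos$sub)))
  can <- canonicalize_smiles(raw, strict = TRUE)
  out <- can[!duplicated(can)]
  .grammar_cache[[key]] <- out
  out
}

#' Specification of a synthetic dataset
#'
#' The defaults define the package's reference study conditions: a
#' 200/100/100 Animalia-dominant class imbalance (mirroring the roughly
#' 2:1 animal-to-microbial ratio of curated marine compound collections)
#' and an 8% one-way microbial-to-Animalia label-noise rate.
#'
#' @param n_animalia,n_bacteria,n_fungi per-class compound counts.
#' @param noise_rate fraction in `[0, 1]` of microbial compounds to relabel
#'   as Animalia when noise is injected.
#' @param seed integer seed; the same spec always yields the same dataset.
#' @param grammar template grammar, see [default_grammar].
#' @param id_prefix string prepended to generated ids (keeps ids disjoint
#'   across several generated datasets, e.g. train/test/pool).
#' @return an object of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(n_animalia = 200, n_bacteria = 100, n_fungi = 100,
                           noise_rate = 0.08, seed = 1,
                           grammar = default_grammar(), id_prefix = "") {
  n <- c(`0` = n_animalia, `1` = n_bacteria, `2` = n_fungi)
  stopifnot(all(n >= 0), noise_rate >= 0, noise_rate <= 1,
            is.numeric(seed), length(seed) == 1)
  structure(list(n_per_class = n, noise_rate = noise_rate,
                 seed = as.integer(seed), grammar = grammar,
                 id_prefix = id_prefix),
            class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat("<synthetic_spec> n =", paste(x$n_per_class, collapse = "/"),
      " noise_rate =", x$noise_rate, " seed =", x$seed, "\n")
  invisible(x)
}

#' Generate a synthetic labeled dataset
#'
#' Samples, without replacement and deterministically in the spec seed, the
#' requested number of distinct molecules per class from the grammar's full
#' canonical enumeration. Labels are the generator's ground truth
#' (`true_label == label`); use [inject_label_noise] to plant misannotations.
#'
#' @param spec a [synthetic_spec].
#' @return an [mnp_dataset] with ids `ani_*`, `bac_*`, `fun_*`.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  prefix <- c(`0` = "ani", `1` = "bac", `2` = "fun")
  ids <- character(0); smi <- character(0); lab <- integer(0)
  for (k in c("0", "1", "2")) {
    n <- spec$n_per_class[[k]]
    if (n == 0) next
    pool <- .enumerate_class(spec$grammar[[k]])
    if (n > length(pool))
      stop("class ", k, ": requested ", n, " molecules but the grammar ",
           "enumerates only ", length(pool),
           " distinct structures; enlarge grammar cores/subs/prefixes",
           call. = FALSE)
    pick <- with_seed(derive_seed(spec$seed, paste0("class", k)),
                      sample(pool, n))
    ids <- c(ids, sprintf("%s%s_%04d", spec$id_prefix %||% "", prefix[[k]],
                          seq_len(n)))
    smi <- c(smi, pick)
    lab <- c(lab, rep(as.integer(k), n))
  }
  mnp_dataset(ids, smi, lab, source = "synthetic", canonicalize = FALSE)
}

#' Plant symbiosis-style label noise
#'
#' Relabels exactly `round(rate * n_microbial)` (half-up) randomly chosen
#' microbial records (labels 1 or 2) as Animalia (label 0). The flip is
#' one-way by design: the misannotation mechanism being emulated is
#' microbial metabolites credited to their animal host, and downstream
#' screening trusts microbial labels. True labels are retained in the
#' `true_label` column for scoring.
#'
#' @param ds an [mnp_dataset] carrying true labels.
#' @param rate flip fraction in `[0, 1]`.
#' @param seed integer seed; same seed, same flips.
#' @return a list with elements `dataset` (the noisy [mnp_dataset]) and
#'   `flipped` (sorted character vector of flipped ids).
#' @export
inject_label_noise <- function(ds, rate, seed = 1) {
  stopifnot(inherits(ds, "mnp_dataset"), rate >= 0, rate <= 1)
  micro <- which(ds$records$label %in% c(1L, 2L))
  n_flip <- as.integer(floor(rate * length(micro) + 0.5))
  flip <- if (n_flip > 0)
    with_seed(derive_seed(seed, "noise"), sample(micro, n_flip)) else integer(0)
  out <- ds
  out$records$label[flip] <- 0L
  list(dataset = out, flipped = sort(ds$records$id[flip]))
}
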