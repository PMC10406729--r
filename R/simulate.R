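#' Default chemical-shift windows for the HSQC simulator
#'
#' Textbook 1H/13C ranges per carbon environment category, each given as
#' `c(h_lo, h_hi, c_lo, c_hi)` in ppm. All windows lie inside the default
#' rasterization frame. The simulator places a carbon's peak at a
#' deterministic position inside its category window (hashed from the
#' radius-2 atom environment), so the windows define realistic geometry,
#' not predicted shifts.
#'
#' @return named list of numeric length-4 vectors.
#' @export
default_shift_windows <- function() {
  list(
    aldehyde_ch     = c(9.3, 10.0, 185, 208),
    aromatic_ch     = c(6.0, 8.5, 100, 150),
    vinyl_ch        = c(5.0, 6.8, 110, 140),
    anomeric_ch     = c(4.3, 5.5, 90, 110),
    o_ch            = c(3.2, 4.6, 55, 90),
    n_ch            = c(2.4, 3.6, 40, 65),
    carbonyl_adj_ch = c(2.0, 3.2, 25, 55),
    ch3             = c(0.5, 2.0, 5, 30),
    ch2             = c(1.0, 2.5, 15, 45),
    ch              = c(1.2, 2.8, 25, 55)
  )
}

#' Simulator configuration
#'
#' @param n_molecules number of molecules to generate.
#' @param noise_sd_h,noise_sd_c Gaussian shift noise sd in ppm (1H / 13C).
#' @param seed integer seed controlling structures, shifts noise and splits.
#' @param shift_windows see [default_shift_windows()].
#' @param split named fractions for the train/val/test partition.
#' @return a `simulator_config` list.
#' @export
simulator_config <- function(n_molecules = 300, noise_sd_h = 0.02,
                             noise_sd_c = 0.4, seed = 1,
                             shift_windows = default_shift_windows(),
                             split = c(train = 0.8, val = 0, test = 0.2)) {
  if (noise_sd_h < 0 || noise_sd_c < 0) abort("noise sds must be >= 0")
  if (n_molecules < 1) abort("n_molecules must be >= 1")
  b <- spectrum_bounds()
  for (w in shift_windows) {
    if (w[1] < b$h_min || w[2] > b$h_max || w[3] < b$c_min || w[4] > b$c_max) {
      abort("shift windows must lie within the default spectrum bounds")
    }
  }
  if (abs(sum(split) - 1) > 1e-8 || any(split < 0)) {
    abort("split fractions must be non-negative and sum to 1")
  }
  structure(
    list(
      n_molecules = as.integer(n_molecules), noise_sd_h = noise_sd_h,
      noise_sd_c = noise_sd_c, seed = as.integer(seed),
      shift_windows = shift_windows, split = split
    ),
    class = "simulator_config"
  )
}

#' Class vocabulary of the synthetic structure grammar
#' @return a [class_vocabulary()] with five natural-product-like classes.
#' @export
synthetic_class_vocabulary <- function() {
  class_vocabulary(
    c("flavonoid", "terpenoid", "polyketide", "alkaloid", "saccharide")
  )
}

.glycosyl <- "(OC1OC(CO)C(O)C(O)C1O)"

# Per-class sprintf templates; every %s slot takes a parenthesised branch
# ("" for unsubstituted). The pools keep all products parseable, neutral,
# CHNO-only, and 50-1500 Da.
.grammar <- list(
  flavonoid = list(
    templates = c(
      "O=c1cc(-c2ccc%scc2)oc2cc%scc%sc12",
      "Oc1cc%scc%sc1C=CC(=O)O",
      "O=C(c1ccc%scc1)c1ccc%scc1%s"
    ),
    subs = c("", "(C)", "(O)", "(OC)", "(CC)"),
    glyc_ok = TRUE
  ),
  terpenoid = list(
    templates = c(
      "CC1(C)CCC%sC(C)%sC1",
      "CC(C)=CCCC%s(C)C=CC%s",
      "CC1CCC2%sC(C)(C)CCC%sC12C"
    ),
    subs = c("", "(C)", "(O)", "(CO)", "(CC)"),
    glyc_ok = TRUE
  ),
  polyketide = list(
    templates = c(
      "CC(=O)CC%sC(O)CC%sC(=O)O",
      "CCC(O)C%sC(=O)CC%sC(C)=O",
      "CC(O)CC(=O)C%sC(O)C%sC=O"
    ),
    subs = c("", "(C)", "(O)", "(CC)", "(CO)"),
    glyc_ok = TRUE
  ),
  alkaloid = list(
    templates = c(
      "CN1CCC%sC(%s)CC1",
      "c1cc%scnc1CC%sN",
      "CN(C)CCc1cc%sc(%s)cc1"
    ),
    subs = c("", "(C)", "(O)", "(OC)"),
    glyc_ok = TRUE
  ),
  saccharide = list(
    templates = c(
      "OCC1OC(O%s)C(O)C(O)C1O",
      "OCC1OC(OC%s)C(O)C(O)C1O",
      "OCC1OC(Oc2ccc%scc2)C(O)C(O)C1O"
    ),
    subs = c("", "(C)", "(CO)", "(CC)"),
    glyc_ok = FALSE # already a glycoside by construction
  )
)

#' Generate random synthetic structures with class labels
#'
#' Assembles SMILES from a bundled fragment grammar (aromatic chromone and
#' phenylpropanoid cores, saturated terpenoid rings, polyketide-like
#' carbonyl chains, N-heterocycles, and glucopyranosides), spanning the
#' five classes of [synthetic_class_vocabulary()] with a glycoside /
#' non-glycoside mix (about a third of non-saccharide molecules carry an
#' O-glucosyl substituent). Classes are assigned round-robin, so any
#' `n >= 5` covers all classes. Deterministic given `seed`.
#'
#' @param n number of structures.
#' @param seed integer seed.
#' @param glyc_prob probability of glycosylating an eligible slot.
#' @return tibble with columns `id`, `smiles`, `class`.
#' @export
generate_structures <- function(n, seed = 1, glyc_prob = 0.3) {
  stopifnot(n >= 1)
  vocab <- synthetic_class_vocabulary()
  withr::with_seed(as.integer(seed), {
    cls <- vocab[((seq_len(n) - 1) %% length(vocab)) + 1]
    smiles <- character(n)
    for (i in seq_len(n)) {
      g <- .grammar[[cls[i]]]
      tmpl <- sample(g$templates, 1)
      nslot <- lengths(regmatches(tmpl, gregexpr("%s", tmpl, fixed = TRUE)))
      subs <- sample(g$subs, nslot, replace = TRUE)
      if (g$glyc_ok && stats::runif(1) < glyc_prob) {
        subs[sample(nslot, 1)] <- .glycosyl
      }
      smiles[i] <- do.call(sprintf, c(list(tmpl), as.list(subs)))
    }
    tibble(
      id = sprintf("syn%04d", seq_len(n)),
      smiles = smiles,
      class = as.character(cls)
    )
  })
}

# Category of a hydrogen-bearing carbon for shift-window lookup.
.carbon_category <- function(mol, a) {
  nb <- mol$adj[[a]]
  ord <- mol$adj_order[[a]]
  el <- mol$elements[nb]
  if (any(el == "O" & ord == 2)) return("aldehyde_ch")
  has_double_c <- any(el == "C" & ord == 2)
  if (mol$ring_atom[a] && has_double_c) return("aromatic_ch")
  if (has_double_c) return("vinyl_ch")
  n_ox <- sum(el == "O")
  if (n_ox >= 2) return("anomeric_ch")
  if (n_ox == 1) return("o_ch")
  if (any(el == "N")) return("n_ch")
  carbonyl_adj <- any(vapply(nb[el == "C"], function(b) {
    any(mol$elements[mol$adj[[b]]] == "O" & mol$adj_order[[b]] == 2)
  }, logical(1)))
  if (carbonyl_adj) return("carbonyl_adj_ch")
  switch(as.character(mol$n_h[a]), "3" = "ch3", "2" = "ch2", "ch")
}

#' Simulate an HSQC peak list for a structure
#'
#' Produces one cross-peak per hydrogen-bearing carbon (quaternary carbons
#' are silent, as in a real HSQC). The noise-free position is a
#' deterministic function of the carbon's radius-2 circular environment:
#' the environment identifier is hashed to a point inside the shift window
#' of the carbon's category, so identical substructures always produce
#' identical peaks — the regularity a spectrum-to-structure network
#' exploits. Gaussian ppm noise with the configured sds is then added
#' (consuming the current RNG state) and shifts are clamped to the default
#' frame. Phase is negative iff the carbon bears exactly two hydrogens.
#' Peaks are ordered by heavy-atom index.
#'
#' @param smiles SMILES string (or a `mol_graph`).
#' @param cfg a [simulator_config()].
#' @param edited logical: mark the result as multiplicity-edited?
#' @return a [peak_list()].
#' @export
#' @examples
#' simulate_hsqc("c1ccccc1", simulator_config(noise_sd_h = 0, noise_sd_c = 0))
simulate_hsqc <- function(smiles, cfg = simulator_config(), edited = FALSE) {
  mol <- if (inherits(smiles, "mol_graph")) smiles else parse_smiles(smiles)
  env <- morgan_environments(mol)
  # deepest available environment id per atom (radius-2 unless saturated)
  top_id <- env |>
    dplyr::group_by(.data$center) |>
    dplyr::slice_max(.data$radius, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  id_of <- stats::setNames(top_id$id, top_id$center)
  carbons <- which(mol$elements == "C" & !mol$is_h & mol$n_h >= 1)
  b <- spectrum_bounds()
  n <- length(carbons)
  h <- c_ <- numeric(n)
  ph <- character(n)
  for (k in seq_len(n)) {
    a <- carbons[k]
    w <- cfg$shift_windows[[.carbon_category(mol, a)]]
    id <- id_of[[as.character(a)]]
    u_h <- .hash_mix(id, 101) / 2147483647
    u_c <- .hash_mix(id, 202) / 2147483647
    h[k] <- w[1] + u_h * (w[2] - w[1])
    c_[k] <- w[3] + u_c * (w[4] - w[3])
    ph[k] <- if (mol$n_h[a] == 2) "negative" else "positive"
  }
  if (n > 0 && (cfg$noise_sd_h > 0 || cfg$noise_sd_c > 0)) {
    h <- h + stats::rnorm(n, sd = cfg$noise_sd_h)
    c_ <- c_ + stats::rnorm(n, sd = cfg$noise_sd_c)
  }
  h <- pmin(pmax(h, b$h_min), b$h_max)
  c_ <- pmin(pmax(c_, b$c_min), b$c_max)
  peak_list(h, c_, ph, 1, edited = edited)
}

#' Build a complete synthetic dataset
#'
#' Generates structures, computes their supervised targets (fingerprint,
#' molecular weight, class, glycoside flag), simulates one HSQC peak list
#' per structure, and draws disjoint train/val/test splits. Fully
#' deterministic given `cfg$seed`.
#'
#' @param cfg a [simulator_config()].
#' @param edited simulate multiplicity-edited spectra?
#' @return an `hsqc_dataset`: list with `examples` (records tibble plus
#'   `peaks` list-column), `splits` (integer index vectors), `vocabulary`,
#'   and `config`.
#' @export
make_dataset <- function(cfg = simulator_config(), edited = FALSE) {
  structures <- generate_structures(cfg$n_molecules, seed = cfg$seed)
  records <- build_records(structures, synthetic_class_vocabulary())
  graphs <- parse_smiles(structures$smiles, ids = structures$id)
  if (inherits(graphs, "mol_graph")) graphs <- list(graphs)
  withr::with_seed(cfg$seed + 1L, {
    peaks <- lapply(graphs, simulate_hsqc, cfg = cfg, edited = edited)
    n <- cfg$n_molecules
    idx <- sample(n)
    n_train <- round(cfg$split[["train"]] * n)
    n_val <- round(cfg$split[["val"]] * n)
    splits <- list(
      train = sort(idx[seq_len(n_train)]),
      val = sort(idx[seq_len(n_val) + n_train]),
      test = sort(idx[setdiff(seq_len(n), seq_len(n_train + n_val))])
    )
  })
  examples <- records
  examples$peaks <- unname(peaks)
  structure(
    list(
      examples = examples, splits = splits,
      vocabulary = synthetic_class_vocabulary(), config = cfg
    ),
    class = "hsqc_dataset"
  )
}

#' @export
print.hsqc_dataset <- function(x, ...) {
  cat(sprintf(
    "<hsqc_dataset> %d examples (train %d / val %d / test %d), %d classes\n",
    nrow(x$examples), length(x$splits$train), length(x$splits$val),
    length(x$splits$test), length(x$vocabulary)
  ))
  invisible(x)
}

#' Write / read a dataset directory
#'
#' Plain-text layout: `structures.tsv` (id, smiles, class, glycoside),
#' `peaks/<id>.tsv` per spectrum, `splits.json`, `config.json`. Reading
#' recomputes fingerprints and molecular weights from the structures, so
#' the directory stays small and text-only.
#'
#' @param ds an `hsqc_dataset`.
#' @param dir output directory.
#' @return `dir`, invisibly (write) or an `hsqc_dataset` (read).
#' @export
write_dataset <- function(ds, dir) {
  dir.create(file.path(dir, "peaks"), recursive = TRUE, showWarnings = FALSE)
  utils::write.table(
    ds$examples[, c("id", "smiles", "class_name", "glycoside")],
    file.path(dir, "structures.tsv"),
    sep = "\t", row.names = FALSE, quote = FALSE
  )
  for (i in seq_len(nrow(ds$examples))) {
    write_peaks(
      ds$examples$peaks[[i]],
      file.path(dir, "peaks", paste0(ds$examples$id[i], ".tsv"))
    )
  }
  jsonlite::write_json(
    ds$splits, file.path(dir, "splits.json"), auto_unbox = FALSE
  )
  cfg <- ds$config
  cfg$shift_windows <- NULL
  jsonlite::write_json(
    c(unclass(cfg), list(edited = is_edited(ds$examples$peaks[[1]]),
                         vocabulary = as.character(ds$vocabulary))),
    file.path(dir, "config.json"),
    auto_unbox = TRUE
  )
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "config.json"), simplifyVector = TRUE)
  structures <- utils::read.table(
    file.path(dir, "structures.tsv"), sep = "\t", header = TRUE,
    colClasses = c("character", "character", "character", "logical")
  )
  names(structures)[names(structures) == "class_name"] <- "class"
  records <- build_records(structures, class_vocabulary(meta$vocabulary))
  records$peaks <- lapply(records$id, function(id) {
    read_peaks(file.path(dir, "peaks", paste0(id, ".tsv")),
               edited = isTRUE(meta$edited))
  })
  splits <- jsonlite::read_json(file.path(dir, "splits.json"), simplifyVector = TRUE)
  cfg <- simulator_config(
    n_molecules = meta$n_molecules, noise_sd_h = meta$noise_sd_h,
    noise_sd_c = meta$noise_sd_c, seed = meta$seed,
    split = stats::setNames(as.numeric(meta$split), c("train", "val", "test"))
  )
  structure(
    list(
      examples = records, splits = lapply(splits, as.integer),
      vocabulary = class_vocabulary(meta$vocabulary), config = cfg
    ),
    class = "hsqc_dataset"
  )
}
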