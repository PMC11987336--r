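# Synthetic reaction fixtures.
#
# Records are built by template joins: reactant core fragments are preserved
# verbatim as substructures of the product (ester/amide/ether/amine
# couplings, acetate deprotection for single-reactant records), so the
# contrastive task has recoverable structure at desk scale.  Every record has
# 1-5 reactants and exactly one product; reagents and numeric attributes
# (yield in percent, temperature in degrees C) appear at configurable rates.

#' Fixture generator configuration
#'
#' @param n_reactions number of records.
#' @param seed RNG seed.
#' @param reactant_count_range inclusive bounds on reactant counts, within
#'   1..5.
#' @param halogen_rate fraction of products carrying halogen atoms.
#' @param reagent_rate fraction of records with reagents.
#' @param yield_rate,temperature_rate attribute presence rates.
#' @return list of class `rxn_fixture_config`.
#' @export
fixture_config <- function(n_reactions = 2000L, seed = 7L,
                           reactant_count_range = c(1L, 5L),
                           halogen_rate = 0.4, reagent_rate = 0.3,
                           yield_rate = 0.9, temperature_rate = 0.8) {
  stopifnot(n_reactions >= 1L,
            reactant_count_range[1] >= 1L, reactant_count_range[2] <= 5L,
            reactant_count_range[1] <= reactant_count_range[2],
            halogen_rate >= 0, halogen_rate <= 1,
            reagent_rate >= 0, reagent_rate <= 1)
  structure(list(n_reactions = as.integer(n_reactions), seed = as.integer(seed),
                 reactant_count_range = as.integer(reactant_count_range),
                 halogen_rate = halogen_rate, reagent_rate = reagent_rate,
                 yield_rate = yield_rate, temperature_rate = temperature_rate),
            class = "rxn_fixture_config")
}

#' Chainable molecular fragment library
#'
#' Each fragment SMILES is valid both at the start of a chain and appended
#' mid-chain (first and last written atoms keep an open valence).  Halogen
#' membership is tagged for scenario bookkeeping.
#'
#' @param seed unused placeholder for interface stability; the library is a
#'   fixed, documented vocabulary.
#' @return data.frame with `smiles` and `halogens` (comma-joined set).
#' @export
generate_fragment_library <- function(seed = 7L) {
  frags <- c(
    "C", "CC", "CCC", "CCCC", "CCCCC", "C(C)C", "CC(C)C",
    "c1ccccc1", "c1ccccc1C", "C1CCCCC1", "CC=CC", "CC#CC", "CCOCC",
    "C(F)C", "C(F)(F)C", "C(Cl)C", "C(Cl)CC", "CC(Cl)C", "C(Br)C",
    "C(I)C", "c1cc(F)ccc1", "c1cc(Cl)ccc1", "c1cc(Br)ccc1", "c1cc(I)ccc1")
  hal <- vapply(frags, function(s) {
    paste(mol_halogen_set(parse_smiles(s)), collapse = ",")
  }, "", USE.NAMES = FALSE)
  data.frame(smiles = frags, halogens = hal, stringsAsFactors = FALSE)
}

.REAGENT_POOL <- c("O", "CO", "CCO", "CC#N", "ClCCl", "c1ccncc1",
                   "CCN(CC)CC", "OS(=O)(=O)O", "[Na+]", "[K+]")

# junction templates: product linker, left reactant terminal, right reactant
# prefix
.JUNCTIONS <- list(
  ester = list(linker = "C(=O)O", left = "C(=O)O", right = "O"),
  amide = list(linker = "C(=O)N", left = "C(=O)O", right = "N"),
  ether = list(linker = "O", left = "Br", right = "O"),
  amine = list(linker = "N", left = "Br", right = "N"))

#' Generate a synthetic reaction dataset
#'
#' @param config an [fixture_config()].
#' @return list of `rxn_record`, length `n_reactions`, seed-deterministic,
#'   all round-trippable through the dataset IO.
#' @export
generate_reactions <- function(config = fixture_config()) {
  lib <- generate_fragment_library()
  plain <- lib$smiles[lib$halogens == ""]
  halo <- lib$smiles[lib$halogens != ""]
  set.seed(config$seed)
  lo <- config$reactant_count_range[1]; hi <- config$reactant_count_range[2]
  kk <- lo:hi
  # weights favor two-reactant couplings, as in curated reaction corpora
  kw <- c(0.15, 0.40, 0.25, 0.12, 0.08)[kk]
  kw <- kw / sum(kw)
  records <- vector("list", config$n_reactions)
  for (i in seq_len(config$n_reactions)) {
    k <- sample(kk, 1L, prob = kw)
    with_halogen <- stats::runif(1) < config$halogen_rate
    cores <- character(k)
    for (j in seq_len(k)) cores[j] <- sample(plain, 1L)
    if (with_halogen) {
      cores[sample.int(k, 1L)] <- sample(halo, 1L)
    }
    if (k == 1L) {
      # halide hydrolysis R-Br -> R-OH: the product closely resembles the
      # reactant, populating the high-Tanimoto class for scenario 3
      reactants <- paste0(cores[1], "CBr")
      product <- paste0(cores[1], "CO")
    } else {
      jn <- sample(names(.JUNCTIONS), k - 1L, replace = TRUE)
      reactants <- character(k)
      product <- cores[1]
      for (j in seq_len(k - 1L)) {
        tpl <- .JUNCTIONS[[jn[j]]]
        left_term <- tpl$left
        right_pre <- tpl$right
        reactants[j] <- paste0(if (j == 1L) "" else .JUNCTIONS[[jn[j - 1L]]]$right,
                               cores[j], left_term)
        product <- paste0(product, tpl$linker, cores[j + 1L])
      }
      reactants[k] <- paste0(.JUNCTIONS[[jn[k - 1L]]]$right, cores[k])
    }
    reagents <- character(0)
    if (stats::runif(1) < config$reagent_rate) {
      reagents <- sample(.REAGENT_POOL, sample(1:2, 1L))
    }
    attrs <- list()
    if (stats::runif(1) < config$yield_rate) {
      attrs$yield <- round(100 * stats::rbeta(1, 5, 2), 1)
    }
    if (stats::runif(1) < config$temperature_rate) {
      attrs$temperature <- round(min(200, max(0, stats::rnorm(1, 80, 30))), 1)
    }
    records[[i]] <- reaction_record(sprintf("fx%05d", i), product, reactants,
                                    reagents, attrs,
                                    meta = list(cores = paste(cores,
                                                              collapse = " ")))
  }
  .assert_scenario_diversity(records)
  records
}

# every preference scenario must admit both positive and negative ratings on
# the generated set
.assert_scenario_diversity <- function(records, sample_n = 150L) {
  sigs <- vapply(records, function(r)
    paste(mol_halogen_set(parse_smiles(r$product)), collapse = ","), "")
  if (length(unique(sigs)) < 2L) {
    stop("fixture lacks halogen-set diversity for scenario 1")
  }
  counts <- vapply(records, function(r) length(r$reactants), 0L)
  if (all(counts == 2L) || !any(counts == 2L)) {
    stop("fixture lacks reactant-count diversity for scenario 2")
  }
  idx <- unique(round(seq(1L, length(records),
                          length.out = min(sample_n, length(records)))))
  tani <- vapply(records[idx], function(r)
    max_tanimoto(r$product, r$reactants), 0)
  if (!any(tani > 0.5) || !any(tani <= 0.5)) {
    stop("fixture lacks Tanimoto diversity for scenario 3")
  }
  invisible(TRUE)
}

#' Generate train/validation/test fixture datasets
#'
#' Desk-scale defaults (2000 / 200 / 200) keep training in CPU minutes while
#' leaving room for metric movement.
#'
#' @param n_train,n_val,n_test split sizes.
#' @param seed generator seed.
#' @param ... further arguments to [fixture_config()].
#' @return list with `train`, `val`, `test` record lists.
#' @export
generate_fixture_datasets <- function(n_train = 2000L, n_val = 200L,
                                      n_test = 200L, seed = 7L, ...) {
  all <- generate_reactions(fixture_config(
    n_reactions = n_train + n_val + n_test, seed = seed, ...))
  list(train = all[seq_len(n_train)],
       val = all[n_train + seq_len(n_val)],
       test = all[n_train + n_val + seq_len(n_test)])
}

#' Sample a query set from held-out records
#'
#' @param dataset list of `rxn_record` (held-out split).
#' @param n number of queries.
#' @param query_type "product_only" or "product_and_reactants".
#' @param seed sampling seed.
#' @param K retrieved records per query.
#' @return list of `rxn_query` (similarity mode).
#' @export
generate_query_set <- function(dataset, n,
                               query_type = c("product_only",
                                              "product_and_reactants"),
                               seed = 7L, K = 30L) {
  query_type <- match.arg(query_type)
  if (n > length(dataset)) stop("n exceeds the dataset size")
  set.seed(seed)
  picks <- sample.int(length(dataset), n)
  lapply(dataset[picks], function(r) {
    query_spec(product = r$product,
               reactants = if (query_type == "product_and_reactants")
                 r$reactants else NULL,
               match_mode = "similarity", K = K)
  })
}
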