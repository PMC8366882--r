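#' Parameters for the survey simulator
#'
#' The generator emulates the structure the identification pipeline
#' relies on: fixed-width COI barcodes, a barcoding gap (within-species
#' divergence well below 1%, between-species divergence above the species
#' boundary), species-specific spawning windows across the sampling
#' season, and a specimen-level amplification-dropout process.
#'
#' @param n_species number of library species (default 10).
#' @param n_families number of families the species are spread over.
#' @param individuals_per_species reference sequences per species.
#' @param barcode_length barcode width in bp (default 569).
#' @param kappa transition/transversion rate ratio of the substitution
#'   process (default 4).
#' @param intraspecific_divergence expected K2P distance between
#'   conspecific sequences (default 0.003).
#' @param interspecific_divergence minimum K2P distance between species
#'   (default 0.03); must exceed `intraspecific_divergence`.
#' @param spawning_windows optional named list, species -> character
#'   vector of active months; drawn at random (contiguous, 1-4 months)
#'   when `NULL`.
#' @param monthly_sampling expected egg count per active species per
#'   month: a single number or a named vector over `months` (default 30).
#' @param dropout_rate probability that a sampled egg yields no usable
#'   sequence (default 0.38, the scale of ethanol-degradation failure in
#'   long-stored collections).
#' @param unknown_species_fraction fraction of eggs drawn from taxa
#'   absent from the reference library (default 0.01).
#' @param months sampling season (default May-September).
#' @param seed integer RNG seed.
#' @return an object of class `simulation_params` (validated list).
#' @export
simulation_params <- function(n_species = 10L, n_families = 4L,
                              individuals_per_species = 3L,
                              barcode_length = 569L, kappa = 4,
                              intraspecific_divergence = 0.003,
                              interspecific_divergence = 0.03,
                              spawning_windows = NULL,
                              monthly_sampling = 30,
                              dropout_rate = 0.38,
                              unknown_species_fraction = 0.01,
                              months = MONTHS_DEFAULT, seed = 1L) {
  p <- list(n_species = as.integer(n_species),
            n_families = as.integer(n_families),
            individuals_per_species = as.integer(individuals_per_species),
            barcode_length = as.integer(barcode_length),
            kappa = as.numeric(kappa),
            intraspecific_divergence = as.numeric(intraspecific_divergence),
            interspecific_divergence = as.numeric(interspecific_divergence),
            spawning_windows = spawning_windows,
            monthly_sampling = monthly_sampling,
            dropout_rate = as.numeric(dropout_rate),
            unknown_species_fraction = as.numeric(unknown_species_fraction),
            months = as.character(months), seed = as.integer(seed))
  stopifnot(p$n_species >= 1L, p$individuals_per_species >= 1L,
            p$barcode_length >= 1L, p$kappa > 0,
            p$intraspecific_divergence >= 0,
            p$intraspecific_divergence < p$interspecific_divergence,
            p$dropout_rate >= 0, p$dropout_rate <= 1,
            p$unknown_species_fraction >= 0, p$unknown_species_fraction <= 1)
  class(p) <- "simulation_params"
  p
}

random_sequence <- function(length) {
  paste(sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = "")
}

#' Evolve a sequence under the Kimura two-parameter process
#'
#' Applies per-site substitution with the exact K2P transition
#' probabilities for the requested expected distance and
#' transition/transversion rate ratio, so that the estimated K2P distance
#' between ancestor and descendant is a consistent estimate of
#' `distance`. Non-ACGT sites are left unchanged.
#'
#' @param ancestor nucleotide string.
#' @param distance expected substitutions per site (>= 0).
#' @param kappa transition/transversion rate ratio.
#' @param seed optional RNG seed (otherwise the current RNG stream is
#'   used).
#' @return the descendant sequence (same length).
#' @export
evolve_sequence <- function(ancestor, distance, kappa = 4, seed = NULL) {
  stopifnot(distance >= 0, kappa > 0)
  if (distance > 1) warning("distance ", distance,
                            " approaches saturation of the K2P model")
  if (distance == 0) return(ancestor)
  with_seed(seed, {
    # rate scaling: d = (alpha + 2 beta) t with kappa = alpha / beta
    bt <- distance / (kappa + 2)
    at <- kappa * bt
    e1 <- exp(-4 * bt)               # transversion decay
    e2 <- exp(-2 * (at + bt))        # transition decay
    p_ts <- 0.25 + 0.25 * e1 - 0.5 * e2
    p_tv <- 0.25 - 0.25 * e1         # each of the two transversion targets
    chars <- strsplit(toupper(ancestor), "", fixed = TRUE)[[1L]]
    idx <- match(chars, c("A", "G", "C", "T"))
    site <- which(!is.na(idx))
    u <- runif(length(site))
    # outcome per site: transition, transversion 1, transversion 2, same
    ts_partner <- c("G", "A", "T", "C")
    tv1 <- c("C", "C", "A", "A")
    tv2 <- c("T", "T", "G", "G")
    out <- chars
    k <- idx[site]
    out[site] <- ifelse(u < p_ts, ts_partner[k],
                 ifelse(u < p_ts + p_tv, tv1[k],
                 ifelse(u < p_ts + 2 * p_tv, tv2[k], chars[site])))
    paste(out, collapse = "")
  })
}

## expected K2P distance between two tips given patristic distances is
## additive, so tip-to-tip divergence targets are set on the tree itself.
scale_tree_min_dist <- function(tree, target) {
  pat <- ape::cophenetic.phylo(tree)
  mn <- min(pat[upper.tri(pat)])
  tree$edge.length <- tree$edge.length * (target / mn)
  tree
}

#' Simulate a reference barcode library
#'
#' Species are arranged on a random tree scaled so every between-species
#' distance exceeds the configured interspecific divergence; sequences
#' evolve along the tree under the K2P process, and conspecific reference
#' individuals diverge from their species ancestor at half the
#' within-species divergence. The realised barcoding gap is
#' rejection-checked (bounded retries) so the library's maximum
#' intraspecific K2P stays below its minimum interspecific K2P.
#'
#' @param params a [simulation_params()] object.
#' @param seed RNG seed (default `params$seed`).
#' @param max_tries rejection-sampling retries for the gap check.
#' @return list with `library` (a `reference_library`), `species`
#'   (character), `ancestors` (named character, species ancestor
#'   sequences), `tree` (the generating species tree) and `params`.
#' @export
simulate_reference <- function(params = simulation_params(),
                               seed = params$seed, max_tries = 20L) {
  stopifnot(inherits(params, "simulation_params"))
  with_seed(seed, {
    n_sp <- params$n_species
    genus_id <- (seq_len(n_sp) + 1L) %/% 2L     # two congeners per genus
    genus_of <- paste0("Genus", genus_id)
    fam_of <- paste0("Family",
                     (genus_id - 1L) %% max(params$n_families, 1L) + 1L)
    species <- paste0(genus_of, " sp",
                      stats::ave(seq_len(n_sp), genus_of, FUN = seq_along))
    for (try in seq_len(max_tries)) {
      root <- random_sequence(params$barcode_length)
      anc <- if (n_sp == 1L) setNames(root, species) else {
        tree <- scale_tree_min_dist(ape::rtree(n_sp, br = runif),
                                    2 * params$interspecific_divergence)
        tree$tip.label <- species[as.integer(sub("^t", "", tree$tip.label))]
        evolve_along_tree(tree, root, params$kappa)
      }
      seqs <- character(0); ids <- character(0); rows <- NULL
      for (s in seq_len(n_sp)) {
        for (i in seq_len(params$individuals_per_species)) {
          id <- sprintf("REF%03d_%d", s, i)
          seqs <- c(seqs, evolve_sequence(anc[[species[s]]],
                                          params$intraspecific_divergence / 2,
                                          params$kappa))
          ids <- c(ids, id)
          rows <- rbind(rows, data.frame(id = id, family = fam_of[s],
                                         genus = genus_of[s],
                                         species = species[s],
                                         stringsAsFactors = FALSE))
        }
      }
      names(seqs) <- ids
      lib <- reference_library(seqs, rows)
      if (barcoding_gap_holds(lib, params)) {
        return(list(library = lib, species = species,
                    ancestors = anc,
                    tree = if (n_sp > 1L) tree else NULL, params = params))
      }
    }
    stop("could not realise the requested barcoding gap after ",
         max_tries, " tries; widen the divergence separation")
  })
}

## evolve the root sequence down a phylo tree; returns tip sequences
evolve_along_tree <- function(tree, root_seq, kappa) {
  n <- length(tree$tip.label)
  seqs <- vector("list", n + tree$Nnode)
  seqs[[n + 1L]] <- root_seq
  ord <- stats::reorder(tree, "cladewise")
  for (e in seq_len(nrow(ord$edge))) {
    from <- ord$edge[e, 1L]; to <- ord$edge[e, 2L]
    seqs[[to]] <- evolve_sequence(seqs[[from]], ord$edge.length[e], kappa)
  }
  setNames(unlist(seqs[seq_len(n)]), tree$tip.label)
}

## realised barcoding gap: max within-species K2P < min between-species K2P
barcoding_gap_holds <- function(lib, params) {
  d <- k2p_matrix(lib$sequences)
  sp <- lib$taxonomy$species
  same <- outer(sp, sp, `==`) & upper.tri(d)
  diff <- outer(sp, sp, `!=`) & upper.tri(d)
  if (!any(diff)) return(TRUE)
  max_intra <- if (any(same)) max(d[same]) else 0
  min(d[diff]) >= params$interspecific_divergence && max_intra < min(d[diff])
}

## contiguous random spawning window of 1-4 months per species
random_windows <- function(species, months) {
  setNames(lapply(species, function(s) {
    len <- sample.int(min(4L, length(months)), 1L)
    start <- sample.int(length(months) - len + 1L, 1L)
    months[start:(start + len - 1L)]
  }), species)
}

#' Simulate a drifting-egg survey
#'
#' Generates a season of dated egg specimens from a simulated reference
#' library: each species sheds eggs only inside its spawning window, egg
#' barcodes diverge from a random conspecific reference lineage at
#' within-species scale, a configurable fraction of eggs comes from taxa
#' absent from the library (off-library lineages at least 5% divergent
#' from every reference), and specimen-level dropout removes each egg's
#' sequence with the configured probability (dropped eggs keep their
#' metadata row, mirroring failed amplification).
#'
#' @param reference output of [simulate_reference()].
#' @param params a [simulation_params()] (default: the reference's).
#' @param seed RNG seed (default `params$seed + 1`).
#' @return list with `sequences` (named character; surviving specimens
#'   only), `metadata` (data.frame: id, specimen_type, month, time_slot,
#'   in_season), `truth` (data.frame: id, species, month, dropped,
#'   in_library), `windows` (named list of active months per species) and
#'   `params`.
#' @export
simulate_survey <- function(reference, params = reference$params,
                            seed = params$seed + 1L) {
  stopifnot(inherits(params, "simulation_params"))
  lib <- reference$library
  months <- params$months
  with_seed(seed, {
    windows <- params$spawning_windows %||%
      random_windows(reference$species, months)
    stopifnot(all(unlist(windows) %in% months))
    rate <- params$monthly_sampling
    if (length(rate) == 1L) rate <- setNames(rep(rate, length(months)), months)
    # Off-library taxa for the unknown-egg fraction: distant relatives of
    # the same locus, evolved from a species ancestor far beyond the
    # species boundary and rejection-checked against every reference.
    unknowns <- character(0)
    if (params$unknown_species_fraction > 0) {
      root <- reference$ancestors[[1L]]
      for (u in 1:2) {
        for (try in 1:20) {
          cand <- evolve_sequence(root, 0.35, params$kappa)
          # pairs beyond the model's range count as far enough
          dmin <- min(vapply(lib$sequences, function(r)
            tryCatch(k2p_distance(align_pair(cand, r)),
                     fisheggs_error = function(e) Inf), numeric(1)))
          if (dmin >= max(0.05, 1.5 * params$interspecific_divergence)) break
        }
        unknowns <- c(unknowns, cand)
      }
      names(unknowns) <- paste0("Offlib sp", seq_along(unknowns))
    }
    blocks <- list(); seq_blocks <- list(); k <- 0L; b <- 0L
    for (mo in months) {
      active <- names(windows)[vapply(windows, function(w) mo %in% w,
                                      logical(1))]
      for (sp in active) {
        n_egg <- rpois(1L, rate[[mo]])
        if (n_egg < 1L) next
        ids <- sprintf("EGG%05d", k + seq_len(n_egg))
        k <- k + n_egg
        off <- length(unknowns) > 0 &
          runif(n_egg) < params$unknown_species_fraction
        src_unk <- if (any(off)) sample(seq_along(unknowns), sum(off),
                                        replace = TRUE)
        ref_ids <- lib$index$species[[sp]]
        parents <- character(n_egg)
        parents[!off] <- unname(lib$sequences[
          sample(ref_ids, sum(!off), replace = TRUE)])
        parents[off] <- unname(unknowns[src_unk])
        eggs <- vapply(parents, evolve_sequence, "",
                       distance = params$intraspecific_divergence / 2,
                       kappa = params$kappa, USE.NAMES = FALSE)
        names(eggs) <- ids
        dropped <- runif(n_egg) < params$dropout_rate
        true_sp <- rep(sp, n_egg)
        true_sp[off] <- names(unknowns)[src_unk]
        b <- b + 1L
        blocks[[b]] <- data.frame(id = ids, species = true_sp, month = mo,
                                  dropped = dropped, in_library = !off,
                                  stringsAsFactors = FALSE)
        seq_blocks[[b]] <- eggs[!dropped]
      }
    }
    truth <- do.call(rbind, blocks) %||%
      data.frame(id = character(), species = character(),
                 month = character(), dropped = logical(),
                 in_library = logical())
    seqs <- unlist(seq_blocks) %||% character(0)
    metadata <- data.frame(id = truth$id, specimen_type = "egg",
                           month = truth$month, time_slot = NA_character_,
                           in_season = TRUE, stringsAsFactors = FALSE)
    list(sequences = seqs, metadata = metadata, truth = truth,
         windows = windows, params = params)
  })
}
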