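# Engineered hit-list archetypes covering every cascade rule and its
# threshold boundaries. Thresholds are strict: identity exactly at a
# bound falls through to the next rule.

cascade_archetypes <- function() {
  list(
    # 1: unambiguous best/second-best species call
    list(hits = make_hits(c("Ga a", "Gb b"), c(0.996, 0.982)),
         level = "species", taxon = "Ga a", rule = "P1_best_second"),
    # 2: runner-up species exactly at the bound is no longer "below" it
    #    -> the species rules fail, the genus floor catches it
    list(hits = make_hits(c("Ga a", "Ga a", "Gb b"), c(0.996, 0.992, 0.990)),
         level = "genus", taxon = "Ga", rule = "F2_genus_floor"),
    # 3: best exactly at the species bound fails every species rule
    list(hits = make_hits(c("Ga a", "Ga a", "Ga a", "Ga a", "Ga a"),
                          c(0.990, 0.99, 0.99, 0.989, 0.988)),
         level = "genus", taxon = "Ga", rule = "F2_genus_floor"),
    # 4: both top species above the bound, same genus -> genus call
    list(hits = make_hits(c("Ga a", "Ga b"), c(0.996, 0.992)),
         level = "genus", taxon = "Ga", rule = "P1_best_second"),
    # 5: both above the bound but different genera -> primary unresolved,
    #    genus majority of the top five decides
    list(hits = make_hits(c("Ga a", "Ga a", "Ga a", "Gc c", "Gc c"),
                          c(0.995, 0.995, 0.994, 0.993, 0.993)),
         level = "genus", taxon = "Ga", rule = "F2_genus_floor"),
    # 6: top-100 consensus: the runner-up species sits outside the top
    #    100, so the consensus species call fires
    list(hits = make_hits(c(rep("Ga a", 100), "Gb b"),
                          c(seq(0.999, 0.992, length.out = 100), 0.9915)),
         level = "species", taxon = "Ga a", rule = "P2_top100"),
    # 7: primary unresolved but the top five agree -> fallback species
    list(hits = make_hits(c(rep("Ga a", 5), "Gb b"),
                          c(0.998, 0.997, 0.996, 0.995, 0.994, 0.992)),
         level = "species", taxon = "Ga a", rule = "F1_top5_species"),
    # 8: top-five consensus without identity above the species bound
    list(hits = make_hits(rep("Ga a", 5), rep(0.99, 5)),
         level = "genus", taxon = "Ga", rule = "F2_genus_floor"),
    # 9: genus floor with a 3-vs-2 species split inside one genus
    list(hits = make_hits(c("Gh d", "Gh d", "Gh d", "Gh e", "Gh e"),
                          c(0.96, 0.958, 0.957, 0.956, 0.955)),
         level = "genus", taxon = "Gh", rule = "F2_genus_floor"),
    # 10: tied genus majority -> unidentified
    list(hits = make_hits(c("Gh d", "Gh d", "Gj f", "Gj f"),
                          c(0.96, 0.958, 0.957, 0.956)),
         level = "unidentified", taxon = "", rule = "F2_genus_floor"),
    # 11: below the genus floor -> unidentified
    list(hits = make_hits(c("Ga a", "Gb b"), c(0.93, 0.91)),
         level = "unidentified", taxon = "", rule = "F3_below_floor"),
    # 12: exactly at the genus floor is not above it
    list(hits = make_hits(c("Ga a", "Gb b"), c(0.95, 0.94)),
         level = "unidentified", taxon = "", rule = "F3_below_floor")
  )
}

run_archetype <- function(arch, cfg = run_config()) {
  res <- assign_primary(arch$hits, cfg)
  if (is.null(res)) res <- assign_fallback(arch$hits, cfg)
  res
}
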