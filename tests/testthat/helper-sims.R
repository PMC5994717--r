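# Shared synthetic fixtures, built once per test session and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# Small 3-strain set with one accessory plasmid each; mutation rate 1%.
small_sim <- function() {
  cached("small_sim", function() {
    generate_strain_set(
      pan_genome_spec(n_families = 40), n_strains = 3, mutation_rate = 0.01,
      replicon_sizes = c(chromosome = 6e4, pSymA = 5e4, pSymB = 5e4,
                         accessory = 2e4),
      n_accessory_range = c(1, 1), seed = 42
    )
  })
}

# The same configuration without mutations.
small_sim_mu0 <- function() {
  cached("small_sim_mu0", function() {
    generate_strain_set(
      pan_genome_spec(n_families = 40), n_strains = 3, mutation_rate = 0,
      replicon_sizes = c(chromosome = 6e4, pSymA = 5e4, pSymB = 5e4,
                         accessory = 2e4),
      n_accessory_range = c(1, 1), seed = 42
    )
  })
}

# Gene families clustered from small_sim (shared across test files).
small_sim_families <- function() {
  cached("small_sim_families", function() cluster_genes(small_sim()$genomes$genes))
}

# Compact 2-strain set with planted repeat families, for the repeat
# pipeline; small replicons keep the self-matching quick.
repeat_sim <- function() {
  cached("repeat_sim", function() {
    sim <- generate_strain_set(
      pan_genome_spec(n_families = 20), n_strains = 2, mutation_rate = 0.01,
      replicon_sizes = c(chromosome = 3e4, pSymA = 25e3, pSymB = 25e3,
                         accessory = 12e3),
      n_accessory_range = c(0, 0), seed = 11
    )
    sim <- plant_repeat_family(sim, consensus_length = 300,
                               copies_per_strain = 4, divergence = 0.02,
                               revcomp_fraction = 0.25, seed = 12)
    sim <- plant_repeat_family(sim, consensus_length = 150,
                               copies_per_strain = 3, divergence = 0.03,
                               revcomp_fraction = 0.5, seed = 13)
    sim
  })
}

repeat_sim_results <- function() {
  cached("repeat_sim_results", function() {
    sim <- repeat_sim()
    fams <- discover_repeat_families(sim$genomes$replicons)
    reps <- sim$genomes$replicons
    inst <- purrr::map_dfr(seq_len(nrow(reps)), function(i) {
      scan_genome(fams, reps$sequence[[i]], reps$replicon_id[[i]], seed = 3)
    })
    list(families = fams, raw = inst, resolved = resolve_overlaps(inst))
  })
}

# Flagship parameter-recovery configuration: 4 strains, 300 kb main
# replicons, one accessory plasmid, 1% per-site divergence, with five
# planted single-gene moves and one planted 100 kb translocation.
flagship_sim <- function(mutation_rate = 0.01, seed = 20240) {
  key <- paste0("flagship_", mutation_rate)
  cached(key, function() build_flagship(mutation_rate, seed))
}

build_flagship <- function(mutation_rate, seed) {
  sim <- generate_strain_set(
    pan_genome_spec(n_families = 100),
    n_strains = 4, mutation_rate = mutation_rate,
    replicon_sizes = c(chromosome = 3e5, pSymA = 3e5, pSymB = 3e5,
                       accessory = 8e4),
    n_accessory_range = c(1, 1), seed = seed
  )
  # translocation first: the single-gene moves then avoid its families
  sim <- plant_translocation(sim, "S04", "chromosome", "pSymB", 1e5,
                             seed = panreplicon:::child_seed(seed, 40))
  moves <- list(c("S01", "chromosome", "pSymB"),
                c("S02", "pSymB", "pSymA"),
                c("S03", "pSymA", "pSymB"),
                c("S04", "pSymB", "pSymA"),
                c("S01", "pSymB", "pSymA"))
  for (k in seq_along(moves)) {
    mv <- moves[[k]]
    sim <- plant_gene_move(sim, mv[1], mv[2], mv[3],
                           seed = panreplicon:::child_seed(seed, 30 + k))
  }
  sim
}

flagship_families <- function() {
  cached("flagship_families",
         function() cluster_genes(flagship_sim()$genomes$genes))
}
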