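# Shared simulated runs, built once per test session and cached.

.run_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .run_cache, inherits = FALSE)) {
    assign(key, force(expr), envir = .run_cache)
  }
  get(key, envir = .run_cache)
}

# Small mixed-cell-line run with realistic noise defaults.
mini_two_lines <- function() {
  cached("mini_two_lines", {
    fx <- fixture_config("two_lines", n_cells = 250, seed = 7)
    dir <- file.path(tempdir(), "mini_two_lines")
    sim <- simulate_experiment(fx$config, fx$schema, dir, seed = 7)
    dmx <- demux_fastq(sim$files$r1, sim$files$r2, fx$schema, fx$config$panel)
    c(fx, sim, list(demux = dmx))
  })
}

# Noise-free run: no sequencing error, no PCR duplication, perfect ligation.
mini_noiseless <- function() {
  cached("mini_noiseless", {
    fx <- fixture_config("two_lines", n_cells = 250, seed = 11,
                         seq_error_rate = 0, mean_reads_per_molecule = 1)
    dir <- file.path(tempdir(), "mini_noiseless")
    sim <- simulate_experiment(fx$config, fx$schema, dir, seed = 11)
    # exact collapse: with no sequencing error the distinct-UMI count is the
    # exact inverse of the simulation (directional would merge the rare pair
    # of true molecules whose random UMIs differ by one base)
    dmx <- demux_fastq(sim$files$r1, sim$files$r2, fx$schema, fx$config$panel,
                       min_umi = 0, collapse = "exact")
    c(fx, sim, list(demux = dmx))
  })
}

# Full-size mixed-cell-line run (1,900 regular cells = 2,000-cell pool),
# the standard benchmarking design; shared by the acceptance checks.
full_two_lines <- function() {
  cached("full_two_lines", {
    fx <- fixture_config("two_lines", seed = 1)
    dir <- file.path(tempdir(), "full_two_lines")
    sim <- simulate_experiment(fx$config, fx$schema, dir, seed = 1)
    dmx <- demux_fastq(sim$files$r1, sim$files$r2, fx$schema, fx$config$panel)
    c(fx, sim, list(demux = dmx))
  })
}

# True per-cell-key UMI counts: regroups the simulator molecule table by
# barcode triple, counting distinct UMIs per (triple, antibody) — the
# quantity a sequencer can observe (two molecules drawing the same UMI are
# indistinguishable). Handles barcode collisions exactly; this is the
# independent regrouping oracle for the demultiplexer.
truth_key_counts <- function(sim, panel) {
  mol <- sim$truth$molecules[sim$truth$molecules$complete]
  cells <- sim$truth$cells
  mol$cell_key <- cells$cell_key[match(mol$cell_id, cells$cell_id)]
  agg <- stats::aggregate(list(n = mol$umi),
                          by = list(cell_key = mol$cell_key,
                                    antibody = mol$antibody),
                          FUN = function(u) length(unique(u)))
  keys <- sort(unique(agg$cell_key))
  m <- matrix(0, length(keys), nrow(panel),
              dimnames = list(keys, panel$name))
  m[cbind(match(agg$cell_key, keys), match(agg$antibody, panel$name))] <- agg$n
  m
}
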