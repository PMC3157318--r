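# Helpers for exercising the lattice internals through the C++ probes.

# Build the cell table the probes expect (0-based coordinates).
grid_cells <- function(x, y, age = 0L, stem = FALSE) {
  data.frame(x = as.integer(x), y = as.integer(y),
             age = as.integer(rep_len(age, length(x))),
             stem = rep_len(stem, length(x)))
}

choose_site <- function(cells, n_cols, n_rows, mx, my, stem_daughter = FALSE) {
  cryptdrift:::.cpp_choose_site(cells, as.integer(n_cols), as.integer(n_rows),
                                as.integer(mx), as.integer(my), stem_daughter)
}

migrate_probe <- function(cells, n_cols, n_rows) {
  cryptdrift:::.cpp_migrate(cells, as.integer(n_cols), as.integer(n_rows))
}

# Initial lattice state: a zero-iteration run exposes the initialised crypt.
init_state <- function(params, mutation = mutation_config("NORMAL"), seed = 1) {
  params$max_iterations <- 0L
  simulate_crypt(params, mutation, seed = seed,
                 stop_on_succession = FALSE, record = "summary")$cells
}
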