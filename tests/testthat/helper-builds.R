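# Shared fixtures: models are deterministic, so expensive builds are
# memoised across test files.

.build_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.build_cache[[key]])) .build_cache[[key]] <- force(expr)
  .build_cache[[key]]
}

cfg0 <- function() pedspine_config()

vert_cached <- function(group, level) {
  cached(sprintf("v:%d:%s", group, level), build_vertebra(group, level))
}

disc_cached <- function(group, pair) {
  cached(sprintf("d:%d:%s", group, pair), build_disc(group, pair))
}

spine_cached <- function(group) {
  cached(sprintf("s:%d", group), assemble_spine(group))
}

dim_names <- c("AVBH", "PVBH", "SVBL", "IVBL", "SVBW", "MVBW", "IVBW")

dim_rows <- function(report) report[report$name %in% dim_names, ]

# closed-form volume of a unit cube opened (rounded) at radius r
rounded_cube_volume <- function(a, r) {
  core <- a - 2 * r
  core^3 + 6 * r * core^2 + 3 * pi * r^2 * core + 4 / 3 * pi * r^3
}
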