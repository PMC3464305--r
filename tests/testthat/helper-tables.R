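## Published reference values used across the tests.
## Fertility-metrics tables: columns are elapsed cycles, sterile proportion,
## median rate, 90th percentile, P(conceive next cycle), P(conceive within
## next 12 cycles), cumulative conception probability.

metric_cols <- c("cycles_elapsed", "prop_sterile", "median_rate", "p90_rate",
                 "p_next_cycle", "p_next_12", "cumulative")

ref_table <- function(...) {
  out <- as.data.frame(rbind(...))
  names(out) <- metric_cols
  out
}

# 5% sterile + Beta(2.3, 3.7)
table2_ref <- ref_table(
  c(0, 0.050, 0.356, 0.633, 0.364, 0.906, 0.000),
  c(1, 0.079, 0.292, 0.551, 0.303, 0.861, 0.364),
  c(3, 0.151, 0.205, 0.431, 0.217, 0.758, 0.670),
  c(6, 0.282, 0.122, 0.314, 0.138, 0.596, 0.823),
  c(9, 0.414, 0.062, 0.237, 0.090, 0.452, 0.879),
  c(12, 0.530, 0.000, 0.183, 0.060, 0.337, 0.906),
  c(18, 0.699, 0.000, 0.112, 0.029, 0.189, 0.928),
  c(24, 0.800, 0.000, 0.067, 0.015, 0.111, 0.938),
  c(35, 0.895, 0.000, 0.012, 0.006, 0.048, 0.944),
  c(36, 0.900, 0.000, 0.000, 0.005, 0.045, 0.944))

# 5% sterile + Beta(1.8, 4.2)
table3_ref <- ref_table(
  c(0, 0.050, 0.264, 0.539, 0.285, 0.856, 0.000),
  c(1, 0.070, 0.218, 0.467, 0.239, 0.812, 0.285),
  c(3, 0.116, 0.157, 0.365, 0.177, 0.724, 0.567),
  c(6, 0.192, 0.103, 0.270, 0.121, 0.601, 0.740),
  c(12, 0.348, 0.046, 0.169, 0.065, 0.407, 0.856),
  c(18, 0.482, 0.010, 0.116, 0.039, 0.277, 0.896),
  c(24, 0.587, 0.000, 0.083, 0.025, 0.193, 0.915),
  c(36, 0.728, 0.000, 0.046, 0.012, 0.101, 0.931))

# 1% sterile + Beta(11, 22)
table4_ref <- ref_table(
  c(0, 0.010, 0.329, 0.440, 0.330, 0.973, 0.000),
  c(1, 0.015, 0.319, 0.427, 0.319, 0.966, 0.330),
  c(3, 0.032, 0.299, 0.404, 0.296, 0.945, 0.684),
  c(6, 0.086, 0.270, 0.372, 0.258, 0.884, 0.884),
  c(9, 0.198, 0.237, 0.341, 0.210, 0.768, 0.950),
  c(12, 0.375, 0.190, 0.308, 0.153, 0.593, 0.973),
  c(18, 0.745, 0.000, 0.228, 0.055, 0.236, 0.987),
  c(24, 0.921, 0.000, 0.000, 0.015, 0.071, 0.989),
  c(36, 0.992, 0.000, 0.000, 0.001, 0.007, 0.990))

# 5% sterile + 85% Beta(11, 22) + 10% Beta(4, 76)
table5_ref <- ref_table(
  c(0, 0.050, 0.312, 0.432, 0.288, 0.879, 0.000),
  c(1, 0.070, 0.294, 0.416, 0.264, 0.839, 0.288),
  c(3, 0.125, 0.250, 0.385, 0.212, 0.735, 0.601),
  c(6, 0.232, 0.062, 0.332, 0.135, 0.553, 0.785),
  c(9, 0.335, 0.036, 0.270, 0.080, 0.398, 0.851),
  c(12, 0.415, 0.024, 0.181, 0.049, 0.297, 0.879),
  c(18, 0.519, 0.000, 0.061, 0.025, 0.198, 0.904),
  c(24, 0.590, 0.000, 0.051, 0.017, 0.152, 0.915),
  c(36, 0.696, 0.000, 0.040, 0.011, 0.101, 0.928))

# cycles to subfertility thresholds for the four preset populations;
# columns follow default_policies() order
table6_ref <- matrix(c(
  10, 11, 9, 14, 8,
  12, 10, 8, 15, 9,
  14, 20, 15, 19, 14,
  7, 12, 8, 12, 7), nrow = 4, byrow = TRUE,
  dimnames = list(paste0("example", 1:4), names(default_policies())))

# ageing population metrics at four starting ages
table7_ref <- ref_table( # age 25
  c(0, 0.010, 0.210, 0.380, 0.223, 0.872, 0.000),
  c(1, 0.013, 0.193, 0.354, 0.206, 0.853, 0.223),
  c(3, 0.021, 0.166, 0.311, 0.178, 0.812, 0.501),
  c(6, 0.036, 0.136, 0.262, 0.146, 0.750, 0.712),
  c(9, 0.058, 0.113, 0.225, 0.122, 0.687, 0.815),
  c(12, 0.086, 0.096, 0.196, 0.103, 0.626, 0.872),
  c(18, 0.159, 0.069, 0.153, 0.075, 0.507, 0.928),
  c(24, 0.249, 0.048, 0.123, 0.055, 0.400, 0.952),
  c(36, 0.467, 0.009, 0.080, 0.029, 0.235, 0.971))

table8_ref <- ref_table( # age 30
  c(0, 0.020, 0.195, 0.367, 0.209, 0.839, 0.000),
  c(1, 0.026, 0.178, 0.341, 0.191, 0.814, 0.209),
  c(3, 0.040, 0.151, 0.297, 0.163, 0.763, 0.473),
  c(6, 0.068, 0.119, 0.246, 0.130, 0.685, 0.677),
  c(9, 0.105, 0.096, 0.208, 0.105, 0.607, 0.781),
  c(12, 0.149, 0.077, 0.179, 0.086, 0.532, 0.839),
  c(18, 0.259, 0.048, 0.134, 0.058, 0.398, 0.898),
  c(24, 0.379, 0.024, 0.102, 0.039, 0.290, 0.925),
  c(36, 0.606, 0.000, 0.059, 0.018, 0.148, 0.947))

table9_ref <- ref_table( # age 35
  c(0, 0.051, 0.147, 0.310, 0.162, 0.733, 0.000),
  c(1, 0.062, 0.133, 0.286, 0.147, 0.700, 0.162),
  c(3, 0.088, 0.109, 0.245, 0.122, 0.635, 0.381),
  c(6, 0.133, 0.082, 0.200, 0.094, 0.544, 0.566),
  c(9, 0.184, 0.062, 0.166, 0.074, 0.460, 0.670),
  c(12, 0.239, 0.046, 0.139, 0.058, 0.387, 0.733),
  c(18, 0.365, 0.021, 0.100, 0.037, 0.268, 0.802),
  c(24, 0.486, 0.002, 0.072, 0.024, 0.184, 0.836),
  c(36, 0.700, 0.000, 0.036, 0.010, 0.085, 0.866))

table10_ref <- ref_table( # age 40
  c(0, 0.166, 0.070, 0.194, 0.087, 0.494, 0.000),
  c(1, 0.185, 0.063, 0.177, 0.079, 0.463, 0.087),
  c(3, 0.225, 0.051, 0.151, 0.065, 0.406, 0.219),
  c(6, 0.284, 0.037, 0.123, 0.050, 0.333, 0.350),
  c(9, 0.344, 0.025, 0.101, 0.039, 0.273, 0.435),
  c(12, 0.402, 0.015, 0.085, 0.031, 0.223, 0.494),
  c(18, 0.516, 0.000, 0.060, 0.019, 0.147, 0.567),
  c(24, 0.614, 0.000, 0.042, 0.012, 0.096, 0.607),
  c(36, 0.772, 0.000, 0.017, 0.005, 0.038, 0.644))

ageing_tables_ref <- list(`25` = table7_ref, `30` = table8_ref,
                          `35` = table9_ref, `40` = table10_ref)

# cycles to thresholds under ageing, by starting age
table11_ref <- matrix(c(
  24, 12, 13, 26, 19,
  18, 10, 10, 21, 14,
  12, 6, 6, 15, 8,
  4, 0, 0, 6, 0), nrow = 4, byrow = TRUE,
  dimnames = list(c("25", "30", "35", "40"), names(default_policies())))

# change in cycles-to-threshold when ageing during the attempt is frozen
table12_ref <- matrix(c(
  2, 0, 1, 2, 1,
  2, 1, 1, 2, 2,
  2, 1, 0, 2, 2,
  1, 0, 0, 2, 1), nrow = 4, byrow = TRUE,
  dimnames = dimnames(table11_ref))

## helpers

# metrics table rows matched to a reference table, as a plain matrix
metrics_vs_ref <- function(tab, ref) {
  m <- tab[match(ref$cycles_elapsed, tab$cycles_elapsed), metric_cols]
  as.matrix(m) - as.matrix(ref)
}

# number of decimal places a published value is printed with
last_decimal <- function(x) {
  s <- sub("0+$", "", sprintf("%.10f", x))
  nchar(strsplit(s, ".", fixed = TRUE)[[1]][2])
}

# first n at which a metric column drops strictly below a threshold
first_below <- function(tab, metric, threshold) {
  hit <- which(tab[[metric]] < threshold)
  if (!length(hit)) NA_integer_ else tab$cycles_elapsed[hit[1L]]
}
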