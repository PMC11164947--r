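# Shared in-code fixtures for the test suite.

# Two well-separated sources mirrored about zero with equal SDs; with a
# zero TEF a consumer at the origin is exactly symmetric between them.
symmetric_sources <- function() {
  data.frame(
    label = c("left", "right"),
    d13c_mean = c(-20, -10), d13c_sd = c(1, 1),
    d15n_mean = c(0, 8), d15n_sd = c(1, 1),
    stringsAsFactors = FALSE
  )
}

symmetric_consumers <- function(n = 4) {
  matrix(c(rep(-15, n), rep(4, n)), n, 2,
         dimnames = list(NULL, c("d13c", "d15n")))
}

# Three-source toy problem with distinct signatures.
toy3_sources <- function() {
  data.frame(
    label = c("a", "b", "c"),
    d13c_mean = c(-24, -16, -10), d13c_sd = c(0.8, 0.6, 1.0),
    d15n_mean = c(1, 6, 2), d15n_sd = c(0.7, 1.0, 0.5),
    stringsAsFactors = FALSE
  )
}

# Detritivore source configuration assembled from the packaged tables.
detritivore_sources <- function() {
  t1 <- load_table1()
  t2 <- rebaseline_table2()
  keep <- c("label", "n", "d13c_mean", "d13c_sd", "d15n_mean", "d15n_sd")
  rbind(
    as.data.frame(t1)[t1$label %in% c("Dead leaves",
                                      "Fungal-infected dead leaves",
                                      "Soil detritus"), keep],
    as.data.frame(t2)[t2$label == "Diaspididae sp.", keep]
  )
}

rebaseline_table2 <- function() {
  t2 <- load_table2()
  rebaseline(t2[t2$baseline == "Dead leaves", ],
             fpo_baselines()[["Dead leaves"]])
}

# Published detritivore and predator diet matrices (posterior mean
# proportions), sources in model row order, consumers in model column
# order.  Used for the >15% flag rule and as reproduction targets.
published_detritivore_means <- function() {
  matrix(
    c(0.034, 0.033, 0.856, 0.077,   # C. detritus
      0.124, 0.668, 0.174, 0.034,   # Cybocephalus sp.
      0.740, 0.007, 0.009, 0.247,   # Liposcelis sp.
      0.034, 0.032, 0.041, 0.892,   # O. plana
      0.079, 0.703, 0.034, 0.186),  # Zygoribatula sp.
    nrow = 4,
    dimnames = list(
      c("Dead leaves", "Fungal-infected dead leaves", "Soil detritus",
        "Diaspididae sp."),
      c("Camponotus detritus", "Cybocephalus sp.", "Liposcelis sp.",
        "Onymacris plana", "Zygoribatula sp.")
    )
  )
}

published_detritivore_sds <- function() {
  matrix(
    c(0.027, 0.026, 0.179, 0.165,
      0.095, 0.169, 0.156, 0.024,
      0.422, 0.005, 0.007, 0.420,
      0.026, 0.023, 0.032, 0.050,
      0.133, 0.349, 0.027, 0.313),
    nrow = 4, dimnames = dimnames(published_detritivore_means())
  )
}

published_predator_means <- function() {
  matrix(
    c(0.452, 0.036, 0.028, 0.028, 0.048, 0.356, 0.051,  # O. plana
      0.650, 0.090, 0.055, 0.119, 0.023, 0.037, 0.026,  # Nanolpium sp.
      0.056, 0.081, 0.149, 0.464, 0.026, 0.190, 0.033,  # Thysanina sp.
      0.061, 0.088, 0.120, 0.078, 0.095, 0.366, 0.192,  # Salticinae sp.
      0.034, 0.040, 0.036, 0.033, 0.047, 0.059, 0.750), # Haltichellinae sp.
    nrow = 7,
    dimnames = list(
      c("Liposcelis sp.", "Diaspididae sp.", "Deltocephalinae sp.",
        "Zygoribatula sp.", "Sibinia sp.", "Cybocephalus sp.",
        "Haplothrips sp."),
      c("Onymacris plana", "Nanolpium sp.", "Thysanina sp.",
        "Salticinae sp.", "Haltichellinae sp.")
    )
  )
}

published_predator_sds <- function() {
  matrix(
    c(0.069, 0.026, 0.019, 0.019, 0.031, 0.080, 0.049,
      0.100, 0.078, 0.046, 0.085, 0.014, 0.029, 0.017,
      0.086, 0.116, 0.216, 0.307, 0.019, 0.252, 0.027,
      0.048, 0.068, 0.100, 0.058, 0.058, 0.166, 0.133,
      0.028, 0.033, 0.028, 0.025, 0.041, 0.077, 0.103),
    nrow = 7, dimnames = dimnames(published_predator_means())
  )
}
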