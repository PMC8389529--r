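Package: pathmetad
Title: Path Collective Variables, Well-Tempered Metadynamics and
    Standard Binding Free Energies from Unbinding Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A semiautomatic pipeline turning a guess (un)binding
    trajectory into a potential of mean force and a standard binding
    free energy. Extracts a principal (approximate minimum free energy)
    path from sampled conformations by regularized k-means, enforces
    uniform interframe RMSD spacing, builds path collective variables
    S(x) and Z(x) with an automatic smoothness parameter, runs
    well-tempered metadynamics on built-in toy systems with exactly
    integrable free energies, reconstructs F(S,Z) from deposited hills
    (own files or the common plain-text HILLS/COLVAR dialect),
    identifies the bound/unbound dividing frame from inflection
    analysis, applies the standard-volume correction using a grid-based
    solvent-excluded-surface volume, and reproduces host-guest and
    kinase benchmark statistics (Pearson, bootstrap Pearson, Spearman,
    RMSE, mean error).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    bio3d,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
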