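Package: aquaperm
Title: Water Permeation and Domain-Motion Analysis for Membrane-Transporter Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for water transport through membrane
    transporters and channels from molecular-dynamics trajectories:
    detection of complete transmembrane permeation events with a
    two-plane/compartment scheme, diffusion (pd) and osmotic (pf)
    permeabilities via the collective-diffusion coordinate n(t) and the
    single-file pf/pd = N + 1 diagnostic, water number-density profiles and
    the channel-opening measure dmin, layered 2D density maps, per-transit
    residence-time, mobility, interaction-energy and force profiles,
    principal-component analysis of coarse-grained domain motion with
    vibrational weights, softness and quasi-harmonic frequencies, and
    windowed correlations linking water flux to domain motion.  Includes
    Brownian-dynamics channel-water and harmonic bead-network generators
    with known ground truth so the whole pipeline is testable without
    external trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
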