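Package: trackline
Title: Objective Footprint Outlines from 3D Surface Models of Fossil Tracks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fully automatic extraction of two-dimensional footprint outlines
    from triangulated 3D surface models of fossil vertebrate tracks. The
    pipeline orients the model by principal component analysis, extracts a
    stack of closed contour lines, establishes point homology across the stack
    via bottleneck detection, traces the outline along the steepest slope of
    the track wall, and smooths it by elliptic Fourier approximation. For
    tridactyl tracks, six landmarks (three digit tips, two hypexes, heel) are
    placed automatically, and trackway samples can be compared through
    Generalized Procrustes Analysis. A synthetic footprint generator with
    analytically known ground truth supports validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    grDevices,
    stats
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    vegan,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
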