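# Monte-Carlo hull-volume oracle, independent of the package's hull code:
# rejection sampling over the unit cube with the point-in-hull test done by
# scipy's Delaunay triangulation (via the system python).
mc_hull_volume_cube <- function(points, n_draws = 1e6, seed = 1) {
  pts_file <- tempfile(fileext = ".csv")
  utils::write.table(points, pts_file, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import sys",
    "import numpy as np",
    "from scipy.spatial import Delaunay",
    "pts = np.loadtxt(sys.argv[1], delimiter=',')",
    "n = int(sys.argv[2]); seed = int(sys.argv[3])",
    "rng = np.random.default_rng(seed)",
    "draws = rng.random((n, pts.shape[1]))",
    "tri = Delaunay(pts)",
    "inside = tri.find_simplex(draws) >= 0",
    "print(float(inside.mean()))"
  ), script)
  out <- system2("python", c(script, pts_file,
                             format(n_draws, scientific = FALSE), seed),
                 stdout = TRUE, stderr = FALSE)
  as.numeric(out[length(out)])
}
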