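"""Neighbor-embedding driver: reads a CSV matrix, writes 2-D coordinates.

Invoked by cartprofiler::embed_2d(); parameters arrive on the command line:
  umap_embed.py <in.csv> <out.csv> <n_neighbors> <min_dist> <seed>
"""
import sys

import numpy as np
import umap


def main() -> None:
    in_csv, out_csv, n_neighbors, min_dist, seed = sys.argv[1:6]
    x = np.loadtxt(in_csv, delimiter=",", ndmin=2)
    reducer = umap.UMAP(
        n_neighbors=int(n_neighbors),
        min_dist=float(min_dist),
        n_components=2,
        metric="euclidean",
        random_state=int(seed),
        init="spectral",
    )
    coords = reducer.fit_transform(x)
    np.savetxt(out_csv, coords, delimiter=",")


if __name__ == "__main__":
    main()
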