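"""Seeded 2-D UMAP embedding of a headerless CSV feature matrix.

Usage: python umap_embed.py in.csv out.csv n_neighbors min_dist metric seed
"""
import sys
import warnings

import numpy as np

warnings.filterwarnings("ignore")


def main(argv):
    in_csv, out_csv = argv[1], argv[2]
    n_neighbors = int(argv[3])
    min_dist = float(argv[4])
    metric = argv[5]
    seed = int(argv[6])
    import umap
    X = np.loadtxt(in_csv, delimiter=",", ndmin=2)
    emb = umap.UMAP(n_components=2, n_neighbors=n_neighbors,
                    min_dist=min_dist, metric=metric, random_state=seed,
                    transform_seed=seed).fit_transform(X)
    np.savetxt(out_csv, emb, delimiter=",", fmt="%.10g")


if __name__ == "__main__":
    main(sys.argv)
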