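"""Coalescent haplotype-pool simulator (msprime backend).

Reads a JSON job description and writes one or more plain-text haplotype
pools.  Pool file format (documented in ?load_haplotype_pool on the R side):

    line 1: H S region_length
    line 2: S site positions in bp (strictly increasing, may be fractional)
    lines 3..H+2: one haplotype per line as a string of S characters 0/1

Job JSON fields:
    n_haplotypes        int, H
    region_length       float, bp
    mutation_rate       float, per bp per generation
    recombination_rate  float, per bp per generation
    epochs              list of {time, size, growth_rate}; time 0 = present,
                        times strictly increasing into the past
    seed                int  (ancestry seed; mutations use seed + 1)
    num_replicates      int, default 1
    out                 output path; with num_replicates > 1 the replicate
                        index is appended as ".<i>"
"""

import json
import sys

import msprime


def build_demography(epochs):
    demo = msprime.Demography()
    first = epochs[0]
    if first.get("time", 0) != 0:
        raise ValueError("first epoch must start at time 0")
    demo.add_population(
        name="pop0",
        initial_size=first["size"],
        growth_rate=first.get("growth_rate", 0.0),
    )
    for ep in epochs[1:]:
        if ep["time"] <= 0:
            raise ValueError("epoch times must be positive and increasing")
        demo.add_population_parameters_change(
            time=ep["time"],
            initial_size=ep["size"],
            growth_rate=ep.get("growth_rate", 0.0),
            population="pop0",
        )
    return demo


def write_pool(ts, region_length, path):
    gm = ts.genotype_matrix()  # sites x haplotypes
    positions = [s.position for s in ts.sites()]
    keep = []
    h = ts.num_samples
    for j in range(gm.shape[0]):
        ones = int(gm[j].sum())
        if 0 < ones < h:
            keep.append(j)
    with open(path, "w") as fh:
        fh.write("%d %d %.10g\n" % (h, len(keep), region_length))
        fh.write(" ".join("%.10g" % positions[j] for j in keep))
        fh.write("\n")
        sub = gm[keep, :]
        for i in range(h):
            fh.write("".join("1" if sub[j, i] else "0" for j in range(len(keep))))
            fh.write("\n")


def main(cfg_path):
    with open(cfg_path) as fh:
        cfg = json.load(fh)
    if cfg["mutation_rate"] < 0 or cfg["recombination_rate"] < 0:
        raise ValueError("rates must be non-negative")
    demo = build_demography(cfg["epochs"])
    nrep = int(cfg.get("num_replicates", 1))
    seed = int(cfg["seed"])
    n_hap = int(cfg["n_haplotypes"])
    if n_hap % 2:
        raise ValueError("n_haplotypes must be even (diploid time scaling)")
    reps = msprime.sim_ancestry(
        samples=n_hap // 2,
        ploidy=2,
        sequence_length=float(cfg["region_length"]),
        recombination_rate=float(cfg["recombination_rate"]),
        demography=demo,
        random_seed=seed,
        num_replicates=nrep,
    )
    for i, ts in enumerate(reps):
        mts = msprime.sim_mutations(
            ts,
            rate=float(cfg["mutation_rate"]),
            model=msprime.BinaryMutationModel(),
            discrete_genome=False,
            random_seed=seed + 1 + i,
        )
        path = cfg["out"] if nrep == 1 else "%s.%d" % (cfg["out"], i + 1)
        write_pool(mts, float(cfg["region_length"]), path)


if __name__ == "__main__":
    main(sys.argv[1])
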