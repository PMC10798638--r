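"""Coalescent simulation backend for the introgression benchmark.

Reads a JSON config describing an instantaneous-unidirectional-admixture
demography and a list of replicate seeds, simulates recombining four-population
genomes with msprime, and writes per-replicate site tables (infinite-sites
positions + 0/1 derived-allele haplotype columns) and the exact introgressed
tracts carried by each sampled P2 haplotype (from migration records).

Usage: python iua_sim.py <config.json> <output_dir>
"""

import collections
import json
import os
import sys

import msprime
import numpy as np

POPS = ["P1", "P2", "P3", "P4"]


def build_demography(cfg):
    dem = msprime.Demography()
    for name in ["P1", "P2", "P3", "P4", "P12", "P123", "ANC"]:
        dem.add_population(name=name, initial_size=cfg["ne"])
    if cfg["f"] > 0:
        dem.add_mass_migration(time=cfg["t_gf"], source="P2", dest="P3",
                               proportion=cfg["f"])
    dem.add_population_split(time=cfg["t_p2"], derived=["P1", "P2"],
                             ancestral="P12")
    dem.add_population_split(time=cfg["t_p3"], derived=["P12", "P3"],
                             ancestral="P123")
    dem.add_population_split(time=cfg["t_p4"], derived=["P123", "P4"],
                             ancestral="ANC")
    dem.sort_events()
    return dem


def merge_intervals(iv):
    iv = sorted(iv)
    out = []
    for lo, hi in iv:
        if out and lo <= out[-1][1]:
            out[-1][1] = max(out[-1][1], hi)
        else:
            out.append([lo, hi])
    return out


def p2_tracts(ts, p2_samples, p2_id, p3_id):
    """Introgressed tracts per P2 sample: migration-record intervals of the
    pulse (source P2 -> dest P3, backwards in time), mapped down to the
    samples with link_ancestors and intersected with the record intervals."""
    mig_iv = collections.defaultdict(list)
    for m in ts.migrations():
        if m.source == p2_id and m.dest == p3_id:
            mig_iv[int(m.node)].append((m.left, m.right))
    tracts = {int(u): [] for u in p2_samples}
    anc_nodes = []
    for node, ivs in mig_iv.items():
        if node in tracts:  # the migrating lineage is the sample itself
            tracts[node].extend(ivs)
        else:
            anc_nodes.append(node)
    if anc_nodes:
        tab = ts.tables.link_ancestors(samples=list(p2_samples),
                                       ancestors=anc_nodes)
        for left, right, parent, child in zip(tab.left, tab.right,
                                              tab.parent, tab.child):
            child = int(child)
            if child not in tracts:
                continue
            for lo, hi in mig_iv[int(parent)]:
                a, b = max(left, lo), min(right, hi)
                if a < b:
                    tracts[child].append((a, b))
    return {u: merge_intervals(v) for u, v in tracts.items()}


def run_replicate(cfg, rep, outdir):
    dem = build_demography(cfg)
    samples = []
    for pop in POPS:
        n = int(cfg["samples"].get(pop, 0))
        if n > 0:
            samples.append(msprime.SampleSet(
                n, population=pop, time=cfg["sample_times"].get(pop, 0.0),
                ploidy=1))
    ts = msprime.sim_ancestry(
        samples=samples, demography=dem,
        sequence_length=cfg["length"],
        recombination_rate=cfg["rec"],
        record_migrations=True,
        random_seed=rep["anc_seed"])
    mts = msprime.sim_mutations(ts, rate=cfg["mu"], discrete_genome=False,
                                random_seed=rep["mut_seed"])

    pop_ids = {p.metadata.get("name"): p.id for p in ts.populations()}
    cols, labels = [], []
    for pop in POPS:
        nodes = [u for u in ts.samples()
                 if ts.node(u).population == pop_ids[pop]]
        for i, u in enumerate(nodes):
            cols.append(u)
            labels.append(f"{pop}_{i + 1}")

    pos = mts.tables.sites.position
    geno = mts.genotype_matrix()  # sites x samples, 0 = ancestral
    geno = geno[:, cols]
    sites_path = os.path.join(outdir, f"sites_{rep['id']}.tsv")
    with open(sites_path, "w") as fh:
        fh.write("pos\t" + "\t".join(labels) + "\n")
        for j in range(len(pos)):
            fh.write(f"{pos[j]:.6f}\t" +
                     "\t".join(str(int(x)) for x in geno[j]) + "\n")

    p2_nodes = [u for u in ts.samples()
                if ts.node(u).population == pop_ids["P2"]]
    tracts = p2_tracts(ts, p2_nodes, pop_ids["P2"], pop_ids["P3"])
    tracts_path = os.path.join(outdir, f"tracts_{rep['id']}.tsv")
    with open(tracts_path, "w") as fh:
        fh.write("hap\tleft\tright\n")
        for i, u in enumerate(p2_nodes):
            for lo, hi in tracts[int(u)]:
                fh.write(f"{i + 1}\t{lo:.6f}\t{hi:.6f}\n")
    return labels


def main():
    cfg_path, outdir = sys.argv[1], sys.argv[2]
    with open(cfg_path) as fh:
        cfg = json.load(fh)
    os.makedirs(outdir, exist_ok=True)
    labels = None
    for rep in cfg["replicates"]:
        labels = run_replicate(cfg, rep, outdir)
    meta = {"columns": labels,
            "replicates": [r["id"] for r in cfg["replicates"]],
            "length": cfg["length"]}
    with open(os.path.join(outdir, "meta.json"), "w") as fh:
        json.dump(meta, fh)


if __name__ == "__main__":
    main()
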