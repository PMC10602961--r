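section,parameter,method,before,after,printed_reduction,recomputed_exception
method_exclusion,ntawss,NA,12.2,3.8,-69,FALSE
method_exclusion,lsa,NA,11.1,6.3,-44,TRUE
method_exclusion,ker,NA,16.2,7.1,-56,FALSE
method_exclusion,mean_vorticity,NA,17.2,13.5,-22,FALSE
segmentation_exclusion,ntawss,bc1,31.4,10.8,-66,FALSE
segmentation_exclusion,lsa,bc1,35.0,14.3,-59,FALSE
segmentation_exclusion,ker,bc1,51.0,11.5,-78,TRUE
segmentation_exclusion,mean_vorticity,bc1,21.8,14.5,-33,FALSE
segmentation_exclusion,ntawss,bc2,23.9,8.7,-64,FALSE
segmentation_exclusion,lsa,bc2,36.9,16.5,-55,FALSE
segmentation_exclusion,ker,bc2,38.7,10.6,-73,FALSE
segmentation_exclusion,mean_vorticity,bc2,19.2,12.9,-33,FALSE
segmentation_exclusion,ntawss,bc3,28.6,12.7,-56,FALSE
segmentation_exclusion,lsa,bc3,37.1,17.2,-54,FALSE
segmentation_exclusion,ker,bc3,47.4,14.1,-70,FALSE
segmentation_exclusion,mean_vorticity,bc3,19.4,13.4,-31,FALSE
segmentation_exclusion,ntawss,bc4,26.2,11.4,-57,TRUE
segmentation_exclusion,lsa,bc4,45.0,20.8,-54,FALSE
segmentation_exclusion,ker,bc4,40.6,17.6,-57,FALSE
segmentation_exclusion,mean_vorticity,bc4,17.6,8.5,-52,FALSE
segmentation_exclusion,ntawss,bc5,21.8,10.1,-53,TRUE
segmentation_exclusion,lsa,bc5,33.8,19.4,-43,FALSE
segmentation_exclusion,ker,bc5,35.7,14.4,-60,FALSE
segmentation_exclusion,mean_vorticity,bc5,15.5,10.2,-34,FALSE
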